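# Extract one frame of a (pixel, channel, slow_time, frame) array without
# accidental dimension dropping.
frame_slice <- function(data, fr, pixels = NULL) {
  a <- if (is.null(pixels)) data[, , , fr, drop = FALSE]
       else data[pixels, , , fr, drop = FALSE]
  dim(a) <- dim(a)[1:3]
  a
}

# Normalized channel-correlation profiles, vectorized across pixels.
# data: complex array (P, M, K). Returns complex matrix (P, max_lag).
# Each per-sample term u_i * Conj(u_{i+m}) / (|u_i||u_{i+m}|) has unit
# modulus; zero-magnitude samples are dropped from the average with the
# divisor reduced accordingly (an all-dropped lag yields 0).
corr_profiles <- function(data, max_lag) {
  d <- dim(data)
  P <- d[1]; M <- d[2]
  stopifnot(max_lag >= 1, max_lag <= M - 1)
  mod <- Mod(data)
  nz <- mod > 0
  uhat <- array(0i, d)
  uhat[nz] <- data[nz] / mod[nz]
  out <- matrix(0i, P, max_lag)
  for (m in seq_len(max_lag)) {
    i1 <- seq_len(M - m)
    prod <- uhat[, i1, , drop = FALSE] * Conj(uhat[, i1 + m, , drop = FALSE])
    nvalid <- rowSums(nz[, i1, , drop = FALSE] & nz[, i1 + m, , drop = FALSE],
                      dims = 1)
    s <- rowSums(prod, dims = 1)
    out[, m] <- ifelse(nvalid > 0, s / pmax(nvalid, 1), 0i)
  }
  out
}

#' Normalized channel-correlation profile of one pixel
#'
#' The normalized correlation between receive-channel signals, averaged
#' over slow time and over all element pairs at each spatial separation
#' (lag) `m`:
#' \deqn{\hat R[m] = \frac{1}{K(M-m)} \sum_{k=1}^{K} \sum_{i=1}^{M-m}
#'   \frac{u_i[k]\, u_{i+m}^*[k]}{|u_i[k]|\,|u_{i+m}[k]|}.}
#' Each per-sample term has unit modulus, so \eqn{|\hat R[m]| \le 1}.
#' Samples with zero magnitude (possible after aggressive filtering) are
#' dropped with the divisor reduced; a lag with no valid terms yields 0.
#' The profile is invariant to scaling all samples by a nonzero complex
#' constant.
#'
#' @param pixel_data Complex matrix `(channel, slow_time)`.
#' @return A `coherence_profile`: complex vector of length `M - 1`
#'   indexed by lag.
#' @export
correlation_profile <- function(pixel_data) {
  stopifnot(is.matrix(pixel_data))
  M <- nrow(pixel_data); K <- ncol(pixel_data)
  if (M < 2) stop("need at least 2 channels")
  if (K < 1) stop("need at least 1 slow-time sample")
  x <- array(pixel_data + 0i, dim = c(1, M, K))
  r <- corr_profiles(x, M - 1)[1, ]
  structure(r, class = "coherence_profile")
}

#' Short-lag spatial coherence of a profile
#'
#' Sums the real part of the correlation profile over lags 1 to `q`. High
#' for coherent on-axis signal (triangle-like profiles), near zero for
#' diffuse clutter and thermal noise.
#'
#' @param profile A [correlation_profile()] result, or a numeric/complex
#'   per-lag vector.
#' @param q Maximum lag, in `1..M-1`. Default 10.
#' @return The SLSC value, bounded by `[-q, q]`.
#' @export
slsc_value <- function(profile, q = 10) {
  r <- unclass(profile)
  if (q < 1 || q > length(r))
    stop("q must lie between 1 and M - 1")
  sum(Re(r[seq_len(q)]))
}

#' Theoretical maximum SLSC in diffuse speckle
#'
#' For a rectangular receive aperture the speckle coherence profile is the
#' triangle `1 - m/M` (van Cittert-Zernike), so the largest SLSC
#' attainable in speckle is `sum_{m=1..q} (1 - m/M) = q - q(q+1)/(2M)`.
#' Used as the reference scale for coherence thresholding.
#'
#' @param M Number of receive channels.
#' @param q Maximum lag, in `1..M-1`.
#' @return The triangle-coherence sum.
#' @export
theoretical_max_slsc <- function(M, q) {
  stopifnot(M >= 2)
  if (q < 1 || q > M - 1) stop("q must lie between 1 and M - 1")
  q - q * (q + 1) / (2 * M)
}

#' SLSC stack across a filter bank
#'
#' Per-pixel, per-filter, per-frame SLSC values measured from the channel
#' data at the output of each clutter filter.
#'
#' @param filtered_datasets List of [channel_ensemble()] objects (one per
#'   filter) sharing the same grid and acquisition.
#' @param q Maximum lag. Default 10.
#' @return An `slsc_stack`: list with `values` (array
#'   `(pixel, filter, frame)`) and `q`.
#' @export
slsc_stack <- function(filtered_datasets, q = 10) {
  stopifnot(length(filtered_datasets) >= 1,
            all(vapply(filtered_datasets, inherits, logical(1),
                       "channel_ensemble")))
  ref <- filtered_datasets[[1]]
  for (ds in filtered_datasets)
    if (!identical(ds$grid, ref$grid) || !identical(dim(ds$data), dim(ref$data)))
      stop("all filtered datasets must share grid and dimensions")
  d <- dim(ref$data)
  vals <- array(NA_real_, c(d[1], length(filtered_datasets), d[4]))
  for (f in seq_along(filtered_datasets)) {
    for (fr in seq_len(d[4])) {
      r <- corr_profiles(frame_slice(filtered_datasets[[f]]$data, fr), q)
      vals[, f, fr] <- rowSums(Re(r))
    }
  }
  structure(list(values = vals, q = q, grid = ref$grid, acq = ref$acq),
            class = "slsc_stack")
}

#' Mean lag-one coherence over an ROI
#'
#' The real part of the lag-one normalized channel correlation, averaged
#' over the pixels of an ROI (and over frames). A scalar clutter/noise
#' level metric: near 1 for clean speckle, decreasing with incoherent
#' clutter and thermal noise.
#'
#' @param dataset A [channel_ensemble()].
#' @param roi An [roi_rect()] or pixel-index vector.
#' @return The mean lag-one coherence, a dimensionless scalar.
#' @export
lag_one_coherence_roi <- function(dataset, roi) {
  stopifnot(inherits(dataset, "channel_ensemble"))
  idx <- roi_pixels(roi, dataset$grid)
  d <- dim(dataset$data)
  loc <- 0
  for (fr in seq_len(d[4])) {
    r1 <- corr_profiles(frame_slice(dataset$data, fr, idx), 1)
    loc <- loc + mean(Re(r1[, 1]))
  }
  loc / d[4]
}
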