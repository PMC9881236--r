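#' Beamsum a channel-data ensemble
#'
#' Coherently sums the (already time-delayed) receive channels at each
#' pixel and slow-time sample. Linear in the input.
#'
#' @param dataset A [channel_ensemble()].
#' @return A [beam_ensemble()] with dimensions `(pixel, slow_time, frame)`.
#' @export
beamsum <- function(dataset) {
  stopifnot(inherits(dataset, "channel_ensemble"))
  d <- dim(dataset$data)
  bs <- colSums(aperm(dataset$data, c(2, 1, 3, 4)))
  dim(bs) <- c(d[1], d[3], d[4])
  beam_ensemble(bs, dataset$grid, dataset$acq)
}

# Lag-one slow-time autocorrelation accumulator per pixel.
# bs: complex matrix (P, K). Returns complex vector of length P.
kasai_accumulator <- function(bs) {
  K <- ncol(bs)
  rowSums(bs[, 2:K, drop = FALSE] * Conj(bs[, 1:(K - 1), drop = FALSE]))
}

# One frame of a (pixel, slow_time, frame) beam array as a (P, K) matrix.
beam_frame <- function(data, fr) {
  b <- data[, , fr, drop = FALSE]
  dim(b) <- dim(b)[1:2]
  b
}

# Truncated box sum over a rectangular pixel kernel on the image grid.
# x: numeric/complex vector per pixel. Returns list(sum, count) vectors.
# Kernel extents are in mm and converted to an odd pixel window; borders
# are truncated (divisor = pixels actually inside).
kernel_box <- function(x, grid, kernel_mm) {
  n_ax <- grid$n_axial; n_lat <- grid$n_lateral
  half <- pmax(0L, as.integer(floor(kernel_mm / (2 * grid$spacing_mm))))
  img <- matrix(x, n_ax, n_lat)
  s <- matrix(if (is.complex(x)) 0i else 0, n_ax, n_lat)
  cnt <- matrix(0, n_ax, n_lat)
  for (da in -half[1]:half[1]) {
    src_a <- max(1, 1 - da):min(n_ax, n_ax - da)
    dst_a <- src_a + da
    for (dl in -half[2]:half[2]) {
      src_l <- max(1, 1 - dl):min(n_lat, n_lat - dl)
      dst_l <- src_l + dl
      s[dst_a, dst_l] <- s[dst_a, dst_l] + img[src_a, src_l]
      cnt[dst_a, dst_l] <- cnt[dst_a, dst_l] + 1
    }
  }
  list(sum = as.vector(s), count = as.vector(cnt))
}

#' Mean slow-time phase shift at one pixel (2-D autocorrelation)
#'
#' Computes the Kasai estimate: the four-quadrant angle of the lag-one
#' slow-time autocorrelation, accumulated over the ensemble and over a
#' spatial kernel centered on the pixel. The four-quadrant angle preserves
#' the full `(-pi, pi]` range that a literal arctangent ratio would fold.
#'
#' @param beams A [beam_ensemble()].
#' @param pixel Pixel index.
#' @param kernel_mm Spatial kernel extent `c(axial, lateral)` in mm, or
#'   `NULL` for a single-pixel kernel.
#' @param frame Frame index (default 1).
#' @return Phase shift in radians, in `(-pi, pi]`. A zero accumulator (no
#'   detectable energy) returns 0.
#' @export
kasai_phase <- function(beams, pixel, kernel_mm = NULL, frame = 1) {
  stopifnot(inherits(beams, "beam_ensemble"))
  if (beams$acq$ensemble < 2) stop("need K >= 2 slow-time samples")
  acc <- kasai_accumulator(beam_frame(beams$data, frame))
  if (!is.null(kernel_mm)) acc <- kernel_box(acc, beams$grid, kernel_mm)$sum
  a <- acc[pixel]
  if (a == 0i) 0 else Arg(a)
}

#' Convert a mean phase shift to an axial velocity
#'
#' `v = -c * PRF * phi / (4 * pi * f0)`, in cm/s. The leading minus makes
#' motion toward the transducer (which advances the demodulated phase in
#' the estimator's convention) come out positive.
#'
#' @param phi Phase shift in radians, `|phi| <= pi`.
#' @param acq An [acq_params()].
#' @return Axial velocity, cm/s.
#' @export
phase_to_velocity <- function(phi, acq) {
  stopifnot(inherits(acq, "acq_params"))
  if (any(abs(phi) > pi + 1e-12)) stop("|phi| must not exceed pi")
  -100 * acq$c * acq$prf * phi / (4 * pi * acq$f0)
}

#' Velocity map from a beamsummed ensemble
#'
#' Applies the 2-D autocorrelation phase estimate and the velocity
#' conversion at every pixel and frame.
#'
#' @param beams A [beam_ensemble()].
#' @param kernel_mm Spatial accumulation kernel `c(axial, lateral)` in mm,
#'   or `NULL` (default) for single-pixel estimation.
#' @param acq Acquisition parameters; defaults to those stored in `beams`.
#' @return A `velocity_map`: list with `v_hat` and `phi_hat` (matrices
#'   `(pixel, frame)`), a logical rejection `mask` (all `FALSE` here;
#'   priority encoding sets it), plus the grid and acquisition.
#' @export
velocity_map <- function(beams, kernel_mm = NULL, acq = beams$acq) {
  stopifnot(inherits(beams, "beam_ensemble"))
  d <- dim(beams$data)
  phi <- matrix(0, d[1], d[3])
  for (fr in seq_len(d[3])) {
    acc <- kasai_accumulator(beam_frame(beams$data, fr))
    if (!is.null(kernel_mm)) acc <- kernel_box(acc, beams$grid, kernel_mm)$sum
    phi[, fr] <- ifelse(acc == 0i, 0, Arg(acc))
  }
  structure(list(v_hat = phase_to_velocity(phi, acq), phi_hat = phi,
                 mask = matrix(FALSE, d[1], d[3]),
                 grid = beams$grid, acq = acq),
            class = "velocity_map")
}

#' @export
print.velocity_map <- function(x, ...) {
  cat(sprintf("Velocity map: %d pixels x %d frame(s), |v| up to %.2f cm/s\n",
              nrow(x$v_hat), ncol(x$v_hat), max(abs(x$v_hat))))
  invisible(x)
}
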