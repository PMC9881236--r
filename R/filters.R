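#' Design a slow-time high-pass clutter filter
#'
#' Butterworth high-pass in the slow-time domain with the cutoff expressed
#' as a fraction of the PRF. The magnitude response is 1/sqrt(2) at the
#' cutoff and exactly zero at DC. When applied with [filter_slow_time()]
#' the filter is projection-initialized: its internal states are seeded so
#' that the polynomial (by default constant) component of a short ensemble
#' produces no output transient.
#'
#' @param cutoff_fraction Half-power frequency as a fraction of the PRF,
#'   in `(0, 0.5)`.
#' @param order Filter order (number of poles). Default 2, which keeps the
#'   impulse response short relative to typical ensembles of 10-16 samples.
#' @param init_order Order of the polynomial subspace annihilated by the
#'   initialization; `0` (the default) removes the transient of the
#'   constant (DC) component. Must be less than `order`, since an order-n
#'   Butterworth high-pass carries n zeros at DC and can annihilate
#'   polynomials only up to degree n - 1.
#' @return A `clutter_filter` object.
#' @export
design_highpass <- function(cutoff_fraction, order = 2, init_order = 0) {
  if (cutoff_fraction <= 0 || cutoff_fraction >= 0.5)
    stop("cutoff_fraction must lie in (0, 0.5)")
  if (order < 1) stop("order must be at least 1")
  if (init_order < 0 || init_order > order - 1)
    stop("init_order must lie in [0, order - 1]")
  # signal::butter normalizes frequency to the Nyquist rate (0.5 * PRF)
  ba <- signal::butter(order, cutoff_fraction / 0.5, type = "high")
  structure(list(cutoff_fraction = cutoff_fraction,
                 order = as.integer(order),
                 init_order = as.integer(init_order),
                 b = as.numeric(ba$b), a = as.numeric(ba$a),
                 kind = "iir_highpass"),
            class = "clutter_filter")
}

#' The "no filter" identity member
#'
#' Encoded with cutoff fraction 0; [filter_slow_time()] returns its input
#' unchanged, so velocity and coherence are measured from the raw channel
#' signals.
#'
#' @return A `clutter_filter` object of kind `"identity"`.
#' @export
identity_filter <- function() {
  structure(list(cutoff_fraction = 0, order = 0L, init_order = 0L,
                 b = 1, a = 1, kind = "identity"),
            class = "clutter_filter")
}

#' @export
print.clutter_filter <- function(x, ...) {
  if (x$kind == "identity") cat("Clutter filter: identity (no filter)\n")
  else cat(sprintf("Clutter filter: order-%d Butterworth high-pass, cutoff %.3g PRF\n",
                   x$order, x$cutoff_fraction))
  invisible(x)
}

#' Assemble an ordered clutter filter bank
#'
#' @param filters List of [design_highpass()] / [identity_filter()] members
#'   with strictly increasing cutoff fractions. At most one identity member
#'   is allowed and it must come first.
#' @return A `clutter_filter_bank` object (a validated list of filters).
#' @export
clutter_filter_bank <- function(filters) {
  stopifnot(length(filters) >= 1,
            all(vapply(filters, inherits, logical(1), "clutter_filter")))
  cut <- vapply(filters, `[[`, numeric(1), "cutoff_fraction")
  if (any(diff(cut) <= 0)) stop("bank cutoffs must be strictly increasing")
  kinds <- vapply(filters, `[[`, character(1), "kind")
  if (sum(kinds == "identity") > 1) stop("at most one identity member")
  if (any(kinds == "identity") && kinds[1] != "identity")
    stop("the identity member must come first")
  structure(filters, class = "clutter_filter_bank")
}

#' Default clutter filter bank
#'
#' The "no filter" identity member followed by 8 high-pass members with
#' cutoff fractions evenly spaced over 0.03 to 0.24 of the PRF; under the
#' [default_acq()] parameters these correspond to velocity cutoffs of 2.0
#' to 15.8 cm/s.
#'
#' @inheritParams design_highpass
#' @return A `clutter_filter_bank` of 9 members.
#' @export
default_bank <- function(order = 2, init_order = 0) {
  cutoffs <- seq(0.03, 0.24, length.out = 8)
  members <- c(list(identity_filter()),
               lapply(cutoffs, design_highpass, order = order,
                      init_order = init_order))
  clutter_filter_bank(members)
}

#' Bank cutoff fractions
#' @param bank A `clutter_filter_bank`.
#' @return Numeric vector of cutoff fractions (0 for the identity member).
#' @export
bank_cutoffs <- function(bank) {
  stopifnot(inherits(bank, "clutter_filter_bank"))
  vapply(bank, `[[`, numeric(1), "cutoff_fraction")
}

#' @export
print.clutter_filter_bank <- function(x, ...) {
  cat(sprintf("Clutter filter bank: %d members, cutoffs {%s} PRF\n",
              length(x), paste(signif(bank_cutoffs(x), 3), collapse = ", ")))
  invisible(x)
}

#' Complex frequency response of a clutter filter
#'
#' @param filter A `clutter_filter`.
#' @param freq_fraction Frequencies as fractions of the PRF (may be
#'   negative; the response is conjugate-symmetric for these real-
#'   coefficient filters).
#' @return Complex response `H` evaluated on the unit circle.
#' @export
filter_response <- function(filter, freq_fraction) {
  stopifnot(inherits(filter, "clutter_filter"))
  if (filter$kind == "identity") return(rep(1 + 0i, length(freq_fraction)))
  z <- exp(-2i * pi * freq_fraction)
  num <- vapply(z, function(zi) sum(filter$b * zi^(seq_along(filter$b) - 1)),
                complex(1))
  den <- vapply(z, function(zi) sum(filter$a * zi^(seq_along(filter$a) - 1)),
                complex(1))
  num / den
}

# Direct-form II transposed recursion, vectorized across series.
# x: complex/numeric matrix (n_series x K); zinit: n_series x order state
# matrix (may be complex). Returns the filtered matrix.
iir_df2t <- function(b, a, x, zinit = NULL) {
  n <- nrow(x); K <- ncol(x); ord <- length(a) - 1
  y <- matrix(0i, n, K)
  z <- if (is.null(zinit)) matrix(0i, n, ord) else zinit
  for (k in seq_len(K)) {
    xk <- x[, k]
    yk <- b[1] * xk + z[, 1]
    if (ord > 1) for (j in seq_len(ord - 1))
      z[, j] <- b[j + 1] * xk + z[, j + 1] - a[j + 1] * yk
    z[, ord] <- b[ord + 1] * xk - a[ord + 1] * yk
    y[, k] <- yk
  }
  y
}

# Projection-initialization map for a filter at ensemble length K.
# Returns the (order x K) matrix A such that initial states z0 = A %*% x
# minimize the output energy of the degree-<=p polynomial component of x.
# Because an order-n Butterworth high-pass has n zeros at z = 1, that
# component is annihilated exactly for p <= n - 1.
projection_init_map <- function(filter, K) {
  ord <- filter$order
  # zero-state responses to the K canonical inputs (real coefficients, so
  # the maps are real)
  Fm <- t(Re(iir_df2t(filter$b, filter$a, diag(K) + 0i)))
  # zero-input responses to unit initial states
  G <- matrix(0, K, ord)
  for (j in seq_len(ord)) {
    zi <- matrix(0i, 1, ord); zi[1, j] <- 1
    G[, j] <- Re(iir_df2t(filter$b, filter$a, matrix(0i, 1, K), zi)[1, ])
  }
  # orthonormal polynomial basis of degree <= init_order
  p <- filter$init_order
  B <- matrix(1 / sqrt(K), K, 1)
  if (p > 0) B <- cbind(B, stats::poly(seq_len(K), degree = p))
  Pmat <- B %*% t(B)
  -qr.coef(qr(G), Fm %*% Pmat)                  # least-squares init map
}

#' Filter a slow-time sequence with projection initialization
#'
#' Applies the clutter filter along slow time. For IIR members the internal
#' states are initialized from the ensemble's projection onto the
#' polynomial (default: constant) subspace, so that a constant complex
#' input of any value yields identically zero output at every slow-time
#' index -- no start-up transient leaks clutter into short ensembles. The
#' identity member returns its input bit-exactly.
#'
#' @param filter A `clutter_filter`.
#' @param series Complex vector of length `K`, or a matrix with `K`
#'   columns holding one series per row.
#' @return Filtered series with the same shape as the input.
#' @export
filter_slow_time <- function(filter, series) {
  stopifnot(inherits(filter, "clutter_filter"))
  if (filter$kind == "identity") return(series)
  vec <- is.null(dim(series))
  x <- if (vec) matrix(series, 1) else series
  K <- ncol(x)
  if (K < filter$order + 1)
    stop(sprintf("ensemble length %d too short for an order-%d filter",
                 K, filter$order))
  A <- projection_init_map(filter, K)
  z0 <- x %*% t(A)
  y <- iir_df2t(filter$b, filter$a, x + 0i, z0)
  if (vec) y[1, ] else y
}

#' Apply a filter bank to a channel-data ensemble
#'
#' Filters every (pixel, channel, frame) slow-time series through each bank
#' member, producing one filtered [channel_ensemble()] per member. The
#' operation is linear in the input data.
#'
#' @param bank A `clutter_filter_bank`.
#' @param dataset A [channel_ensemble()].
#' @return A list of `channel_ensemble` objects, one per bank member, in
#'   bank order.
#' @export
apply_bank <- function(bank, dataset) {
  stopifnot(inherits(bank, "clutter_filter_bank"),
            inherits(dataset, "channel_ensemble"))
  lapply(bank, apply_filter, dataset = dataset)
}

#' Apply a single clutter filter to a channel-data ensemble
#'
#' @param filter A `clutter_filter`.
#' @param dataset A [channel_ensemble()].
#' @return The filtered `channel_ensemble`.
#' @export
apply_filter <- function(filter, dataset) {
  stopifnot(inherits(filter, "clutter_filter"),
            inherits(dataset, "channel_ensemble"))
  if (filter$kind == "identity") return(dataset)
  d <- dim(dataset$data)
  x <- aperm(dataset$data, c(1, 2, 4, 3))      # bring slow time last
  dim(x) <- c(d[1] * d[2] * d[4], d[3])
  y <- filter_slow_time(filter, x)
  dim(y) <- c(d[1], d[2], d[4], d[3])
  channel_ensemble(aperm(y, c(1, 2, 4, 3)), dataset$grid, dataset$acq)
}
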