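#' Per-frame ROI statistics of a velocity image
#'
#' Mean, population standard deviation, and spatial standard error of the
#' velocities inside an ROI, per frame. Pixels rejected by priority
#' encoding or coherence thresholding are excluded by default (their count
#' is reported); set `include_rejected = TRUE` to average their zeros in.
#'
#' @param x A `color_flow_image` or `velocity_map`.
#' @param roi An [roi_rect()] or pixel-index vector.
#' @param frames Frame indices (default: all).
#' @param include_rejected Include rejected (zeroed) pixels in the
#'   statistics.
#' @return A data.frame with columns `frame`, `mean`, `sd`, `stderr`,
#'   `n`, `n_rejected`.
#' @export
roi_stats <- function(x, roi, frames = NULL, include_rejected = FALSE) {
  v <- if (inherits(x, "color_flow_image")) x$velocity
       else if (inherits(x, "velocity_map")) x$v_hat
       else stop("x must be a color_flow_image or velocity_map")
  mask <- x$mask
  idx <- roi_pixels(roi, x$grid)
  if (is.null(frames)) frames <- seq_len(ncol(v))
  rows <- lapply(frames, function(fr) {
    vals <- v[idx, fr]
    rej <- mask[idx, fr]
    keep <- if (include_rejected) rep(TRUE, length(vals)) else !rej
    if (!any(keep))
      return(data.frame(frame = fr, mean = NA_real_, sd = NA_real_,
                        stderr = NA_real_, n = 0L,
                        n_rejected = sum(rej)))
    vv <- vals[keep]
    m <- mean(vv)
    s <- sqrt(mean((vv - m)^2))                  # population normalization
    data.frame(frame = fr, mean = m, sd = s, stderr = s / sqrt(length(vv)),
               n = length(vv), n_rejected = sum(rej))
  })
  do.call(rbind, rows)
}

#' Mean envelope image of a beamsummed ensemble
#'
#' Per-pixel mean beamsum magnitude across the ensemble -- the B-mode-like
#' amplitude image used for contrast measurements.
#'
#' @param beams A [beam_ensemble()].
#' @return Matrix `(pixel, frame)` of mean envelope amplitudes.
#' @export
envelope_image <- function(beams) {
  stopifnot(inherits(beams, "beam_ensemble"))
  d <- dim(beams$data)
  out <- matrix(NA_real_, d[1], d[3])
  for (fr in seq_len(d[3]))
    out[, fr] <- rowMeans(Mod(beam_frame(beams$data, fr)))
  out
}

#' Amplitude contrast between two ROIs
#'
#' `20 log10(mean envelope in roi_a / mean envelope in roi_b)` -- the
#' amplitude-convention contrast, e.g. between an anechoic region (clutter
#' only) and nearby speckle (clutter plus signal).
#'
#' @param envelope Per-pixel envelope amplitudes (a vector, or a matrix
#'   whose first column/frame is used).
#' @param roi_a,roi_b ROIs ([roi_rect()] or pixel indices).
#' @param grid The [image_grid()].
#' @return Contrast in dB.
#' @export
contrast_db <- function(envelope, roi_a, roi_b, grid) {
  env <- if (is.matrix(envelope)) envelope[, 1] else envelope
  a <- mean(env[roi_pixels(roi_a, grid)])
  b <- mean(env[roi_pixels(roi_b, grid)])
  if (b <= 0) stop("reference ROI has zero mean envelope")
  20 * log10(a / b)
}

#' Computational cost model
#'
#' The expected floating point operations of the adaptive pipeline for
#' `M` channels, `K` slow-time samples, and `F` clutter filters scale as
#' `F*K*M^2 + F*K^2*M + F*K*M` (coherence calculation, clutter filtering,
#' channel summation), against `K*M + K^2` for conventional processing
#' (one channel sum plus one filtering operation).
#'
#' @param M Channels.
#' @param K Slow-time samples.
#' @param F Clutter filters.
#' @return A `flop_model` object.
#' @export
flop_model <- function(M, K, F) {
  stopifnot(M >= 1, K >= 1, F >= 1)
  structure(list(M = M, K = K, F = F), class = "flop_model")
}

#' Slowdown ratio of the adaptive pipeline over conventional processing
#'
#' `(F*K*M^2 + F*K^2*M + F*K*M) / (K*M + K^2)`. For a 64-channel system
#' with a 14-sample ensemble and 8 filters this is roughly 520.
#'
#' @param model A [flop_model()].
#' @return The dimensionless FLOP ratio.
#' @export
flop_ratio <- function(model) {
  stopifnot(inherits(model, "flop_model"))
  M <- model$M; K <- model$K; F <- model$F
  (F * K * M^2 + F * K^2 * M + F * K * M) / (K * M + K^2)
}

#' Structural operation count of the implemented pipeline
#'
#' Counts the complex multiply-accumulates each stage of this package's
#' implementation actually performs per pixel (full-lag coherence,
#' projection-initialized order-`order` IIR filtering including the
#' initialization product, channel summation, and the lag-one
#' autocorrelation), as a sanity check of the asymptotic cost model.
#'
#' @inheritParams flop_model
#' @param order IIR filter order.
#' @param q Maximum coherence lag; defaults to `M - 1` (full lag, as the
#'   asymptotic model assumes).
#' @return List with `adaptive`, `conventional`, and their `ratio`.
#' @export
instrumented_flop_count <- function(M, K, F, order = 2, q = M - 1) {
  filt <- M * (K * (2 * order + 1) + order * K)   # recursion + state init
  norm <- M * K                                   # per-sample normalization
  coh <- K * sum(M - seq_len(q)) * 2              # products + accumulation
  csum <- K * M
  kasai <- K - 1
  adaptive <- F * (filt + norm + coh + csum) + kasai
  conventional <- csum + (K * (2 * order + 1) + order * K) + kasai
  list(adaptive = adaptive, conventional = conventional,
       ratio = adaptive / conventional)
}

#' Total duration of a multi-frame acquisition
#'
#' @param n_frames Number of frames (may be 0).
#' @param frame_rate Frame rate, Hz.
#' @return Duration in seconds.
#' @export
acquisition_duration <- function(n_frames, frame_rate) {
  stopifnot(n_frames >= 0, frame_rate > 0)
  n_frames / frame_rate
}
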