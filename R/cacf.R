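#' Per-pixel filter selection by maximum coherence
#'
#' At each pixel (and frame), selects the bank member whose post-filter
#' SLSC -- optionally weighted per filter -- is largest. Ties are broken
#' toward the lowest cutoff (the identity member first), the conservative
#' choice that preserves slow flow.
#'
#' @param stack An [slsc_stack()] whose filter layers align with `bank`.
#' @param bank The `clutter_filter_bank` that produced the stack.
#' @param weights Optional non-negative weight per bank member (not all
#'   zero); `NULL` for the plain argmax.
#' @return A `selection_map`: list with `index` and `cutoff_fraction`
#'   matrices `(pixel, frame)` and `max_slsc`, the (unweighted) stack
#'   value at the chosen filter.
#' @export
select_filters <- function(stack, bank, weights = NULL) {
  stopifnot(inherits(stack, "slsc_stack"), inherits(bank, "clutter_filter_bank"))
  nf <- dim(stack$values)[2]
  if (nf != length(bank)) stop("stack layers do not match the bank size")
  if (is.null(weights)) weights <- rep(1, nf)
  if (length(weights) != nf) stop("need one weight per bank member")
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be non-negative and not all zero")
  d <- dim(stack$values)
  idx <- matrix(NA_integer_, d[1], d[3])
  mx <- matrix(NA_real_, d[1], d[3])
  for (fr in seq_len(d[3])) {
    w <- stack$values[, , fr, drop = FALSE]
    dim(w) <- d[1:2]
    w <- sweep(w, 2, weights, `*`)
    sel <- max.col(w, ties.method = "first")
    idx[, fr] <- sel
    mx[, fr] <- stack$values[cbind(seq_len(d[1]), sel, fr)]
  }
  cutoffs <- bank_cutoffs(bank)
  structure(list(index = idx,
                 cutoff_fraction = matrix(cutoffs[idx], nrow(idx), ncol(idx)),
                 max_slsc = mx),
            class = "selection_map")
}

new_color_flow_image <- function(velocity, selection, mask, grid, acq, q) {
  structure(list(velocity = velocity, selection = selection, mask = mask,
                 grid = grid, acq = acq, q = q),
            class = "color_flow_image")
}

#' @export
print.color_flow_image <- function(x, ...) {
  cat(sprintf("Color flow image: %d pixels x %d frame(s), %.1f%% rejected\n",
              nrow(x$velocity), ncol(x$velocity), 100 * mean(x$mask)))
  invisible(x)
}

#' Coherence-adaptive color flow image
#'
#' The adaptive pipeline: the channel ensemble is passed through every
#' member of the clutter filter bank; SLSC is measured from the post-filter
#' channel data of each member; each member's output is beamsummed and
#' converted to a velocity map; at each pixel the filter maximizing the
#' (optionally weighted) SLSC is selected and its velocity mapped to the
#' output. Optionally, pixels whose maximum SLSC falls below a fraction of
#' the theoretical speckle maximum are thresholded.
#'
#' @param dataset A [channel_ensemble()].
#' @param bank A `clutter_filter_bank` (default [default_bank()]).
#' @param q Maximum coherence lag (default 10).
#' @param weights Optional per-filter selection weights; see
#'   [select_filters()].
#' @param coherence_threshold_fraction Fraction of
#'   [theoretical_max_slsc()] below which pixels are thresholded; 0
#'   (default) disables thresholding.
#' @param threshold_mode What to do with sub-threshold pixels:
#'   `"reject"` (zero velocity, mask raised) or `"identity"` (assign the
#'   no-filter velocity).
#' @param kernel_mm Spatial kernel for velocity estimation, or `NULL` for
#'   single-pixel estimates.
#' @return A `color_flow_image` with fields `velocity` (cm/s,
#'   `(pixel, frame)`), `selection` (a `selection_map`), and `mask`.
#' @export
cacf_image <- function(dataset, bank = default_bank(), q = 10, weights = NULL,
                       coherence_threshold_fraction = 0,
                       threshold_mode = c("reject", "identity"),
                       kernel_mm = NULL) {
  stopifnot(inherits(dataset, "channel_ensemble"),
            inherits(bank, "clutter_filter_bank"))
  threshold_mode <- match.arg(threshold_mode)
  if (coherence_threshold_fraction < 0 || coherence_threshold_fraction > 1)
    stop("coherence_threshold_fraction must lie in [0, 1]")
  d <- dim(dataset$data)
  P <- d[1]; nf <- d[4]; n_filt <- length(bank)
  slsc <- array(NA_real_, c(P, n_filt, nf))
  vels <- array(NA_real_, c(P, n_filt, nf))
  for (f in seq_len(n_filt)) {
    filtered <- apply_filter(bank[[f]], dataset)
    for (fr in seq_len(nf)) {
      r <- corr_profiles(frame_slice(filtered$data, fr), q)
      slsc[, f, fr] <- rowSums(Re(r))
    }
    vm <- velocity_map(beamsum(filtered), kernel_mm)
    vels[, f, ] <- vm$v_hat
  }
  stack <- structure(list(values = slsc, q = q, grid = dataset$grid,
                          acq = dataset$acq),
                     class = "slsc_stack")
  sel <- select_filters(stack, bank, weights)
  velocity <- matrix(NA_real_, P, nf)
  for (fr in seq_len(nf))
    velocity[, fr] <- vels[cbind(seq_len(P), sel$index[, fr], fr)]
  img <- new_color_flow_image(velocity, sel, matrix(FALSE, P, nf),
                              dataset$grid, dataset$acq, q)
  if (coherence_threshold_fraction > 0) {
    if (threshold_mode == "reject") {
      img <- coherence_threshold(img, stack, coherence_threshold_fraction,
                                 dataset$acq$n_channels)
    } else {
      thr <- coherence_threshold_fraction *
        theoretical_max_slsc(dataset$acq$n_channels, q)
      below <- sel$max_slsc < thr
      id_layer <- which(bank_cutoffs(bank) == 0)[1]
      if (is.na(id_layer))
        stop("threshold_mode = 'identity' requires an identity bank member")
      for (fr in seq_len(nf)) {
        img$velocity[below[, fr], fr] <- vels[below[, fr], id_layer, fr]
        img$selection$index[below[, fr], fr] <- id_layer
        img$selection$cutoff_fraction[below[, fr], fr] <- 0
      }
    }
  }
  img
}

#' Coherence thresholding of a color flow image
#'
#' Rejects pixels whose maximum SLSC across the bank falls below a given
#' fraction of the theoretical maximum SLSC in speckle -- a guard against
#' the high-variance filter selections that arise where coherence is low
#' everywhere (deep noise, focusing errors).
#'
#' @param image A `color_flow_image` from [cacf_image()].
#' @param stack The [slsc_stack()] used for selection (only `max_slsc`
#'   from the image's selection is needed; the stack supplies `q`).
#' @param fraction Threshold as a fraction of [theoretical_max_slsc()],
#'   in `[0, 1]`.
#' @param M Channel count used for the theoretical maximum.
#' @return The thresholded `color_flow_image`.
#' @export
coherence_threshold <- function(image, stack, fraction, M) {
  stopifnot(inherits(image, "color_flow_image"))
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  if (fraction == 0) return(image)
  thr <- fraction * theoretical_max_slsc(M, stack$q)
  below <- image$selection$max_slsc < thr
  image$velocity[below] <- 0
  image$mask <- image$mask | below
  image
}

#' Conventional color flow image
#'
#' The fixed-filter baseline: a single clutter filter, beamsummation,
#' 2-D autocorrelation velocity estimation, and optional priority
#' encoding. (The filter is applied per channel before the beamsum; both
#' maps are linear, so this equals filtering the beamsum.)
#'
#' @param dataset A [channel_ensemble()].
#' @param filter A single `clutter_filter`.
#' @param priority Optional [priority_config()].
#' @param kernel_mm Spatial kernel for velocity estimation.
#' @return A `color_flow_image` (with `selection = NULL`). The filtered
#'   beamsum is attached as attribute `"beams"` for power encoding and
#'   envelope measurements.
#' @export
conventional_image <- function(dataset, filter, priority = NULL,
                               kernel_mm = NULL) {
  stopifnot(inherits(dataset, "channel_ensemble"),
            inherits(filter, "clutter_filter"))
  beams <- beamsum(apply_filter(filter, dataset))
  vmap <- velocity_map(beams, kernel_mm)
  if (!is.null(priority)) {
    vmap <- variance_encode(vmap, priority)
    vmap <- power_encode(vmap, beams, priority)
  }
  img <- new_color_flow_image(vmap$v_hat, NULL, vmap$mask,
                              dataset$grid, dataset$acq, NA_integer_)
  attr(img, "beams") <- beams
  img
}
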