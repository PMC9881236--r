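#' Priority encoding configuration
#'
#' Thresholds for rejecting unreliable color flow pixels. The variance
#' threshold is expressed as a velocity spread in mm/s (squared internally
#' before comparison with the kernel velocity variance); the power
#' threshold is in dB relative to the image-maximum pixel ensemble power.
#' Both are applied over a rectangular spatial kernel, 2 x 2 mm by
#' default.
#'
#' @param variance_threshold Velocity spread sigma, mm/s; `NULL` disables
#'   variance thresholding.
#' @param power_threshold Power threshold P in dB (must be `<= 0`);
#'   `NULL` disables power thresholding.
#' @param kernel_mm Kernel extent `c(axial, lateral)`, mm.
#' @return A `priority_config` object.
#' @export
priority_config <- function(variance_threshold = NULL, power_threshold = NULL,
                            kernel_mm = c(2, 2)) {
  if (!is.null(variance_threshold) && variance_threshold < 0)
    stop("variance_threshold must be non-negative")
  if (!is.null(power_threshold) && power_threshold > 0)
    stop("power_threshold is relative to the image maximum and must be <= 0 dB")
  stopifnot(length(kernel_mm) == 2, all(kernel_mm > 0))
  structure(list(variance_threshold = variance_threshold,
                 power_threshold = power_threshold,
                 kernel_mm = as.numeric(kernel_mm)),
            class = "priority_config")
}

#' Variance thresholding of a velocity map
#'
#' For each pixel, computes the kernel mean and the population variance of
#' the velocities inside the kernel (in mm/s) and rejects the pixel --
#' velocity set to 0 and the rejection mask raised -- where the variance
#' exceeds `sigma^2`. Eliminates regions of spatially random estimates
#' (jitter). Kernels are truncated at image borders. With the threshold
#' disabled the map passes through unchanged.
#'
#' @param vmap A [velocity_map()].
#' @param config A [priority_config()].
#' @return The encoded `velocity_map`; rejected pixels are zeroed and
#'   flagged in `$mask`.
#' @export
variance_encode <- function(vmap, config) {
  stopifnot(inherits(vmap, "velocity_map"), inherits(config, "priority_config"))
  sigma <- config$variance_threshold
  if (is.null(sigma)) return(vmap)
  for (fr in seq_len(ncol(vmap$v_hat))) {
    v_mms <- vmap$v_hat[, fr] * 10               # cm/s -> mm/s
    bx <- kernel_box(v_mms, vmap$grid, config$kernel_mm)
    bx2 <- kernel_box(v_mms^2, vmap$grid, config$kernel_mm)
    kmean <- bx$sum / bx$count
    kvar <- bx2$sum / bx$count - kmean^2
    reject <- kvar > sigma^2
    vmap$v_hat[reject, fr] <- 0
    vmap$mask[reject, fr] <- TRUE
  }
  vmap
}

# Kernel-mean ensemble power normalized to the image-max pixel power, dB.
# beams: beam_ensemble; returns matrix (pixel, frame). Normalization is
# per frame.
normalized_power_db <- function(beams, kernel_mm) {
  d <- dim(beams$data)
  out <- matrix(-Inf, d[1], d[3])
  for (fr in seq_len(d[3])) {
    p_pix <- rowSums(Mod(beam_frame(beams$data, fr))^2)
    p_max <- max(p_pix)
    if (p_max == 0) next
    kmean <- if (is.null(kernel_mm)) p_pix else {
      bx <- kernel_box(p_pix, beams$grid, kernel_mm)
      bx$sum / bx$count
    }
    out[, fr] <- 10 * log10(kmean / p_max)
  }
  out
}

#' Power thresholding of a velocity map
#'
#' For each pixel, the kernel-mean ensemble power of the clutter-filtered
#' beamsum signals, normalized by the image-maximum pixel ensemble power,
#' is compared in dB against the threshold `P`; pixels below it are
#' rejected. Removes low-amplitude echoes from noise or residual clutter.
#' An all-zero frame rejects every pixel (with a warning).
#'
#' @param vmap A [velocity_map()].
#' @param beams The [beam_ensemble()] of clutter-filtered signals the map
#'   was estimated from.
#' @param config A [priority_config()].
#' @return The encoded `velocity_map`.
#' @export
power_encode <- function(vmap, beams, config) {
  stopifnot(inherits(vmap, "velocity_map"), inherits(beams, "beam_ensemble"),
            inherits(config, "priority_config"))
  p_db <- config$power_threshold
  if (is.null(p_db)) return(vmap)
  pw <- normalized_power_db(beams, config$kernel_mm)
  if (any(apply(pw, 2, function(col) all(col == -Inf))))
    warning("all-zero frame: every pixel rejected by the power threshold")
  reject <- pw < p_db
  vmap$v_hat[reject] <- 0
  vmap$mask <- vmap$mask | reject
  vmap
}

#' Sweep priority-encoding thresholds
#'
#' Applies every combination of variance and power thresholds to a
#' velocity map and summarizes the mean velocity and retained-pixel
#' fraction inside and outside a vessel ROI -- the trade-off between
#' artifact suppression and flow preservation.
#'
#' @param vmap A [velocity_map()] (no prior encoding).
#' @param beams The matching clutter-filtered [beam_ensemble()].
#' @param sigma_list Variance thresholds, mm/s.
#' @param power_list Power thresholds, dB.
#' @param roi_in,roi_out ROIs inside and outside the vessel.
#' @param kernel_mm Encoding kernel, mm.
#' @return A list with `maps` (encoded maps indexed `[[sigma]][[power]]`)
#'   and `summary`, a tidy data.frame with columns `sigma`, `power_db`,
#'   `roi`, `frame`, `mean_velocity`, `mean_abs_velocity`,
#'   `retained_fraction`.
#' @export
priority_sweep <- function(vmap, beams, sigma_list, power_list,
                           roi_in, roi_out, kernel_mm = c(2, 2)) {
  maps <- list()
  rows <- list()
  idx_in <- roi_pixels(roi_in, vmap$grid)
  idx_out <- roi_pixels(roi_out, vmap$grid)
  for (si in seq_along(sigma_list)) {
    maps[[si]] <- list()
    for (pi in seq_along(power_list)) {
      cfg <- priority_config(variance_threshold = sigma_list[si],
                             power_threshold = power_list[pi],
                             kernel_mm = kernel_mm)
      enc <- power_encode(variance_encode(vmap, cfg), beams, cfg)
      maps[[si]][[pi]] <- enc
      for (roi_name in c("in", "out")) {
        idx <- if (roi_name == "in") idx_in else idx_out
        for (fr in seq_len(ncol(enc$v_hat))) {
          v <- enc$v_hat[idx, fr]
          kept <- !enc$mask[idx, fr]
          rows[[length(rows) + 1]] <- data.frame(
            sigma = sigma_list[si], power_db = power_list[pi],
            roi = roi_name, frame = fr,
            mean_velocity = mean(v),
            mean_abs_velocity = mean(abs(v)),
            retained_fraction = mean(kept))
        }
      }
    }
  }
  list(maps = maps, summary = do.call(rbind, rows))
}
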