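#' Rectangular pixel grid
#'
#' A plain axial-by-lateral rectangular grid of pixel centers in mm. Pixels
#' are indexed column-major (axial index varies fastest), matching R matrix
#' layout, so a per-pixel vector of length `n_axial * n_lateral` reshapes
#' directly into an image matrix with `matrix(x, n_axial, n_lateral)`.
#'
#' @param n_axial,n_lateral Grid dimensions, pixels.
#' @param spacing_mm Pixel pitch as `c(axial, lateral)`, mm.
#' @param origin_mm Position of the first pixel center, `c(axial, lateral)`
#'   in mm.
#' @return An `image_grid` object.
#' @export
image_grid <- function(n_axial, n_lateral, spacing_mm = c(0.4, 0.4),
                       origin_mm = c(0, 0)) {
  stopifnot(n_axial >= 1, n_lateral >= 1, all(spacing_mm > 0),
            length(spacing_mm) == 2, length(origin_mm) == 2)
  structure(list(n_axial = as.integer(n_axial),
                 n_lateral = as.integer(n_lateral),
                 spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("Grid: %d x %d pixels, %.3g x %.3g mm pitch\n",
              x$n_axial, x$n_lateral, x$spacing_mm[1], x$spacing_mm[2]))
  invisible(x)
}

n_pixels <- function(grid) grid$n_axial * grid$n_lateral

#' Pixel-center coordinates of a grid
#'
#' @param grid An [image_grid()].
#' @return A data.frame with columns `pixel`, `axial_mm`, `lateral_mm`.
#' @export
grid_coordinates <- function(grid) {
  stopifnot(inherits(grid, "image_grid"))
  ax <- grid$origin_mm[1] + (seq_len(grid$n_axial) - 1) * grid$spacing_mm[1]
  lat <- grid$origin_mm[2] + (seq_len(grid$n_lateral) - 1) * grid$spacing_mm[2]
  data.frame(pixel = seq_len(n_pixels(grid)),
             axial_mm = rep(ax, times = grid$n_lateral),
             lateral_mm = rep(lat, each = grid$n_axial))
}

#' Rectangular region of interest
#'
#' @param axial_mm,lateral_mm Closed intervals `c(lo, hi)` in grid
#'   coordinates, mm. Pixels whose centers fall inside both intervals
#'   belong to the ROI.
#' @return An `roi` object.
#' @export
roi_rect <- function(axial_mm, lateral_mm) {
  stopifnot(length(axial_mm) == 2, length(lateral_mm) == 2,
            axial_mm[1] <= axial_mm[2], lateral_mm[1] <= lateral_mm[2])
  structure(list(axial_mm = as.numeric(axial_mm),
                 lateral_mm = as.numeric(lateral_mm)),
            class = "roi")
}

#' Resolve an ROI to pixel indices
#'
#' @param roi An [roi_rect()] or an integer vector of pixel indices.
#' @param grid The [image_grid()] the ROI lives on.
#' @return Integer vector of pixel indices. Errors if empty or out of
#'   bounds.
#' @export
roi_pixels <- function(roi, grid) {
  stopifnot(inherits(grid, "image_grid"))
  if (is.numeric(roi)) {
    idx <- as.integer(roi)
    if (length(idx) == 0) stop("ROI is empty")
    if (any(idx < 1) || any(idx > n_pixels(grid)))
      stop("ROI pixel indices out of grid bounds")
    return(idx)
  }
  stopifnot(inherits(roi, "roi"))
  co <- grid_coordinates(grid)
  idx <- which(co$axial_mm >= roi$axial_mm[1] & co$axial_mm <= roi$axial_mm[2] &
               co$lateral_mm >= roi$lateral_mm[1] &
               co$lateral_mm <= roi$lateral_mm[2])
  if (length(idx) == 0) stop("ROI contains no pixels on this grid")
  idx
}

#' Channel-data ensemble
#'
#' The universal currency of the pipeline: focused (time-delayed) complex
#' baseband IQ receive samples indexed by pixel, receive element, slow-time
#' sample, and frame.
#'
#' @param data Complex array with dimensions
#'   `(pixel, channel, slow_time, frame)`. A 3-D array is promoted to a
#'   single frame.
#' @param grid The [image_grid()] the pixel dimension indexes.
#' @param acq The [acq_params()] of the acquisition; the channel and
#'   slow-time dimensions must equal `acq$n_channels` and `acq$ensemble`.
#' @return A `channel_ensemble` object.
#' @export
channel_ensemble <- function(data, grid, acq) {
  stopifnot(inherits(grid, "image_grid"), inherits(acq, "acq_params"))
  if (!is.complex(data)) data <- data + 0i
  if (length(dim(data)) == 3) dim(data) <- c(dim(data), 1L)
  d <- dim(data)
  if (length(d) != 4)
    stop("channel data must have dimensions (pixel, channel, slow_time, frame)")
  if (d[1] != n_pixels(grid))
    stop("pixel dimension does not match the grid")
  if (d[2] != acq$n_channels)
    stop(sprintf("channel dimension %d != M = %d", d[2], acq$n_channels))
  if (d[3] != acq$ensemble)
    stop(sprintf("slow-time dimension %d != K = %d", d[3], acq$ensemble))
  if (any(!is.finite(Re(data))) || any(!is.finite(Im(data))))
    stop("channel data must be finite")
  structure(list(data = data, grid = grid, acq = acq),
            class = "channel_ensemble")
}

#' @export
print.channel_ensemble <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Channel ensemble: %d pixels x %d channels x %d slow-time x %d frame(s)\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Beamsummed ensemble
#'
#' Complex beamsum samples indexed by pixel, slow-time sample, and frame.
#' Usually produced by [beamsum()].
#'
#' @param data Complex array `(pixel, slow_time, frame)`; a matrix is
#'   promoted to a single frame.
#' @inheritParams channel_ensemble
#' @return A `beam_ensemble` object.
#' @export
beam_ensemble <- function(data, grid, acq) {
  stopifnot(inherits(grid, "image_grid"), inherits(acq, "acq_params"))
  if (!is.complex(data)) data <- data + 0i
  if (length(dim(data)) == 2) dim(data) <- c(dim(data), 1L)
  d <- dim(data)
  if (length(d) != 3)
    stop("beam data must have dimensions (pixel, slow_time, frame)")
  if (d[1] != n_pixels(grid)) stop("pixel dimension does not match the grid")
  if (d[2] != acq$ensemble)
    stop(sprintf("slow-time dimension %d != K = %d", d[2], acq$ensemble))
  if (any(!is.finite(Re(data))) || any(!is.finite(Im(data))))
    stop("beam data must be finite")
  structure(list(data = data, grid = grid, acq = acq),
            class = "beam_ensemble")
}
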