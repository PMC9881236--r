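CONTAINER_VERSION <- "1.0"

acq_to_list <- function(acq) {
  list(f0_hz = acq$f0, prf_hz = acq$prf, sound_speed_m_s = acq$c,
       n_channels = acq$n_channels, ensemble = acq$ensemble,
       frame_rate_hz = acq$frame_rate, n_frames = acq$n_frames)
}

acq_from_list <- function(x) {
  required <- c("f0_hz", "prf_hz", "sound_speed_m_s", "n_channels",
                "ensemble", "frame_rate_hz", "n_frames")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0)
    stop("container is missing acquisition attribute(s): ",
         paste(missing, collapse = ", "))
  acq_params(f0 = x$f0_hz, prf = x$prf_hz, c = x$sound_speed_m_s,
             n_channels = x$n_channels, ensemble = x$ensemble,
             frame_rate = x$frame_rate_hz, n_frames = x$n_frames)
}

#' Write a channel-data ensemble to an HDF5 container
#'
#' Lossless single-file storage of a [channel_ensemble()] together with
#' its acquisition metadata and, when present, the generating scene and
#' seed as provenance. Layout: `/channel_data/real` and
#' `/channel_data/imag` (float64, pixel x channel x slow_time x frame;
#' HDF5 has no native complex type here), `/grid/...`, a JSON acquisition
#' attribute, `/provenance/scene_yaml` and `/provenance/seed`, and a root
#' `container_version` attribute.
#'
#' @param dataset A [channel_ensemble()].
#' @param path Output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_channel_container <- function(dataset, path) {
  stopifnot(inherits(dataset, "channel_ensemble"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "channel_data")
  rhdf5::h5write(Re(dataset$data), path, "channel_data/real")
  rhdf5::h5write(Im(dataset$data), path, "channel_data/imag")
  rhdf5::h5createGroup(path, "grid")
  g <- dataset$grid
  rhdf5::h5write(c(g$n_axial, g$n_lateral), path, "grid/shape")
  rhdf5::h5write(g$spacing_mm, path, "grid/spacing_mm")
  rhdf5::h5write(g$origin_mm, path, "grid/origin_mm")
  scene <- attr(dataset, "scene")
  rhdf5::h5createGroup(path, "provenance")
  if (!is.null(scene)) {
    rhdf5::h5write(scene_to_yaml(scene), path, "provenance/scene_yaml")
    rhdf5::h5write(scene$seed, path, "provenance/seed")
  }
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(CONTAINER_VERSION, fid, "container_version")
  acq_json <- as.character(jsonlite::toJSON(acq_to_list(dataset$acq),
                                            auto_unbox = TRUE))
  rhdf5::h5writeAttribute(acq_json, fid, "acquisition_json")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read a channel-data ensemble from an HDF5 container
#'
#' Validates the container version and required attributes, then
#' reconstructs the [channel_ensemble()] bit-exactly. Any scene
#' provenance is re-attached as the `"scene"` attribute.
#'
#' @param path Path to a file written by [write_channel_container()].
#' @return A [channel_ensemble()].
#' @export
read_channel_container <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  at <- rhdf5::h5readAttributes(path, "/")
  if (is.null(at$container_version))
    stop("not a channel container: missing 'container_version' attribute")
  ver <- as.character(at$container_version)
  if (ver != CONTAINER_VERSION)
    stop(sprintf("unsupported container version '%s' (expected '%s')",
                 ver, CONTAINER_VERSION))
  if (is.null(at$acquisition_json))
    stop("container is missing the 'acquisition_json' attribute")
  acq <- acq_from_list(jsonlite::fromJSON(as.character(at$acquisition_json)))
  shape <- rhdf5::h5read(path, "grid/shape")
  grid <- image_grid(shape[1], shape[2],
                     spacing_mm = rhdf5::h5read(path, "grid/spacing_mm"),
                     origin_mm = rhdf5::h5read(path, "grid/origin_mm"))
  re <- rhdf5::h5read(path, "channel_data/real")
  im <- rhdf5::h5read(path, "channel_data/imag")
  out <- channel_ensemble(complex(real = re, imaginary = im) |>
                            array(dim = dim(re)), grid, acq)
  contents <- rhdf5::h5ls(path)$name
  if ("scene_yaml" %in% contents)
    attr(out, "scene") <- scene_from_yaml(rhdf5::h5read(path,
                                                        "provenance/scene_yaml"))
  out
}

#' Serialize a scene specification to YAML
#'
#' @param scene A [scene_spec()].
#' @return A YAML string.
#' @export
scene_to_yaml <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  x <- unclass(scene)
  if (!is.null(x$anechoic)) x$anechoic <- unclass(x$anechoic)
  yaml::as.yaml(x)
}

#' Deserialize a scene specification from YAML
#'
#' @param text A YAML string (or the path of a YAML file via
#'   [read_scene_yaml()]).
#' @return A [scene_spec()].
#' @export
scene_from_yaml <- function(text) {
  x <- yaml::yaml.load(text)
  anech <- if (is.null(x$anechoic)) NULL
           else roi_rect(x$anechoic$axial_mm, x$anechoic$lateral_mm)
  scene_spec(n_axial = x$n_axial, n_lateral = x$n_lateral,
             spacing_mm = unlist(x$spacing_mm),
             speckle = x$speckle, vessel = x$vessel, clutter = x$clutter,
             noise = x$noise, anechoic = anech, seed = x$seed)
}

#' @rdname scene_from_yaml
#' @param path Path to a YAML scene file.
#' @export
read_scene_yaml <- function(path) {
  scene_from_yaml(paste(readLines(path), collapse = "\n"))
}

#' Read a filter bank specification from YAML
#'
#' Expects a mapping with `cutoffs` (fractions of the PRF; 0 encodes the
#' identity member) and optional `order` and `init_order`.
#'
#' @param path Path to a YAML file.
#' @return A `clutter_filter_bank`.
#' @export
read_bank_yaml <- function(path) {
  x <- yaml::yaml.load_file(path)
  if (is.null(x$cutoffs)) stop("bank YAML must contain 'cutoffs'")
  order <- if (is.null(x$order)) 2 else x$order
  init_order <- if (is.null(x$init_order)) 0 else x$init_order
  members <- lapply(as.numeric(x$cutoffs), function(f) {
    if (f == 0) identity_filter()
    else design_highpass(f, order = order, init_order = init_order)
  })
  clutter_filter_bank(members)
}

#' Write a color flow image to an HDF5 container
#'
#' Stores velocity, rejection mask, and (for adaptive images) the filter
#' selection index, chosen cutoff fraction, and maximum SLSC as parallel
#' pixel-by-frame grids.
#'
#' @param image A `color_flow_image`.
#' @param path Output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_image_container <- function(image, path) {
  stopifnot(inherits(image, "color_flow_image"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(image$velocity, path, "velocity_cms")
  rhdf5::h5write(image$mask * 1L, path, "rejected")
  if (!is.null(image$selection)) {
    rhdf5::h5write(image$selection$index, path, "filter_index")
    rhdf5::h5write(image$selection$cutoff_fraction, path, "cutoff_fraction")
    rhdf5::h5write(image$selection$max_slsc, path, "max_slsc")
  }
  g <- image$grid
  rhdf5::h5write(c(g$n_axial, g$n_lateral), path, "grid_shape")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(CONTAINER_VERSION, fid, "container_version")
  acq_json <- as.character(jsonlite::toJSON(acq_to_list(image$acq),
                                            auto_unbox = TRUE))
  rhdf5::h5writeAttribute(acq_json, fid, "acquisition_json")
  rhdf5::H5Fclose(fid)
  invisible(path)
}
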