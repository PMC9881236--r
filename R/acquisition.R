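#' Acquisition parameters for a color flow ensemble
#'
#' Bundles the acquisition constants that every processing stage needs:
#' transmit center frequency, pulse repetition frequency (PRF), sound speed,
#' receive channel count, slow-time ensemble size, and the frame schedule.
#'
#' @param f0 Transmit center frequency, Hz.
#' @param prf Pulse repetition frequency, Hz. The slow-time axis is sampled
#'   at this rate.
#' @param c Sound speed, m/s. Defaults to the soft-tissue convention of
#'   1540 m/s.
#' @param n_channels Number of receive elements `M` retained after
#'   apodization. Must be at least 2.
#' @param ensemble Slow-time ensemble size `K` (firings per imaging
#'   location per frame). Must be at least 2.
#' @param frame_rate Frame rate, Hz.
#' @param n_frames Number of consecutively acquired frames.
#'
#' @return An object of class `acq_params`.
#' @seealso [default_acq()] for a representative abdominal preset.
#' @export
acq_params <- function(f0, prf, c = 1540, n_channels = 64, ensemble = 14,
                       frame_rate = 12, n_frames = 1) {
  vals <- c(f0 = f0, prf = prf, c = c, n_channels = n_channels,
            ensemble = ensemble, frame_rate = frame_rate, n_frames = n_frames)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all acquisition parameters must be finite and strictly positive")
  if (ensemble < 2) stop("ensemble size K must be at least 2")
  if (n_channels < 2) stop("channel count M must be at least 2")
  structure(list(f0 = f0, prf = prf, c = c,
                 n_channels = as.integer(n_channels),
                 ensemble = as.integer(ensemble),
                 frame_rate = frame_rate,
                 n_frames = as.integer(n_frames)),
            class = "acq_params")
}

#' Representative abdominal color flow acquisition
#'
#' A 3.5 MHz curvilinear acquisition with a 14-sample ensemble at 3 kHz PRF,
#' 64 receive channels, and 20 frames at 12 Hz. These are the package-wide
#' defaults for simulation and for unit conversions.
#'
#' @param n_frames Number of frames (default 1; use 20 for a full cine
#'   acquisition).
#' @return An `acq_params` object.
#' @export
default_acq <- function(n_frames = 1) {
  acq_params(f0 = 3.5e6, prf = 3000, c = 1540, n_channels = 64,
             ensemble = 14, frame_rate = 12, n_frames = n_frames)
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf("Acquisition: f0 = %.3g MHz, PRF = %.3g kHz, c = %g m/s\n",
              x$f0 / 1e6, x$prf / 1e3, x$c))
  cat(sprintf("  M = %d channels, K = %d ensemble, %d frame(s) at %g Hz\n",
              x$n_channels, x$ensemble, x$n_frames, x$frame_rate))
  invisible(x)
}

#' Convert a clutter filter cutoff to a velocity cutoff
#'
#' A high-pass cutoff at a fraction `f_c` of the PRF removes axial
#' velocities below `v_c = c * (f_c * PRF) / (2 * f0)`. Under the default
#' acquisition the bank cutoffs 0.03 and 0.24 of the PRF correspond to
#' 2.0 and 15.8 cm/s.
#'
#' @param cutoff_fraction Cutoff frequency as a dimensionless fraction of
#'   the PRF, in `[0, 0.5)`.
#' @param acq An [acq_params()] object.
#' @return Velocity cutoff in cm/s.
#' @export
cutoff_to_velocity <- function(cutoff_fraction, acq) {
  stopifnot(inherits(acq, "acq_params"))
  if (any(cutoff_fraction < 0) || any(cutoff_fraction >= 0.5))
    stop("cutoff_fraction must lie in [0, 0.5)")
  100 * acq$c * (cutoff_fraction * acq$prf) / (2 * acq$f0)
}

#' Nyquist velocity of an acquisition
#'
#' The largest unambiguous axial velocity, `c * PRF / (4 * f0)`; a mean
#' slow-time phase shift of pi radians maps here.
#'
#' @inheritParams cutoff_to_velocity
#' @return Velocity in cm/s.
#' @export
nyquist_velocity <- function(acq) {
  stopifnot(inherits(acq, "acq_params"))
  100 * acq$c * acq$prf / (4 * acq$f0)
}

#' Mean axial velocity from a volumetric flow setting
#'
#' Converts a pump flow rate through a cylindrical vessel to the mean axial
#' velocity sensed by the beam: the cross-section-averaged flow speed scaled
#' by the cosine of the Doppler angle.
#'
#' @param volume_rate Volumetric flow, mL/min.
#' @param vessel_diameter Vessel diameter, mm.
#' @param doppler_angle Angle between beam axis and flow direction, degrees
#'   in `[0, 90]`.
#' @return Mean axial velocity, cm/s.
#' @export
mean_axial_velocity_from_flow <- function(volume_rate, vessel_diameter,
                                          doppler_angle) {
  if (volume_rate <= 0) stop("volume_rate must be positive")
  if (vessel_diameter <= 0) stop("vessel_diameter must be positive")
  if (doppler_angle < 0 || doppler_angle > 90)
    stop("doppler_angle must lie in [0, 90] degrees")
  q_cm3_s <- volume_rate / 60                      # mL/min -> cm^3/s
  area_cm2 <- pi * (vessel_diameter / 20)^2        # mm diameter -> cm radius
  (q_cm3_s / area_cm2) * cos(doppler_angle * pi / 180)
}

#' Doppler shift of an axial velocity
#'
#' Inverse of the velocity conversion: `f_d = 2 * f0 * v / c`. Velocities
#' beyond the Nyquist velocity alias and are flagged with a warning.
#'
#' @param v_axial Axial velocity, cm/s.
#' @inheritParams cutoff_to_velocity
#' @return Doppler shift in Hz.
#' @export
doppler_shift <- function(v_axial, acq) {
  stopifnot(inherits(acq, "acq_params"))
  v_nyq <- nyquist_velocity(acq)
  if (any(abs(v_axial) > v_nyq + 1e-9))
    warning("axial velocity beyond the Nyquist velocity: estimate will alias")
  2 * acq$f0 * (v_axial / 100) / acq$c
}
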