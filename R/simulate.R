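#' Receive-aperture coherence profiles
#'
#' `triangle_coherence()` is the van Cittert-Zernike prediction for diffuse
#' scattering through a rectangular receive aperture: coherence falls
#' linearly from 1 at lag 0 to 0 at lag `M`. It models speckle and blood.
#' `damped_triangle_coherence()` multiplies the triangle by
#' `exp(-m / m0)`, a faster-decaying profile used for weakly-coherent
#' clutter (reverberation, off-axis scattering); `m0 = Inf` recovers the
#' full triangle and models correlated clutter. `delta_coherence()` is
#' channel-independent thermal noise.
#'
#' @param M Number of receive channels.
#' @param m0 Coherence decay length in lags.
#' @return Numeric vector `rho[m]` for lags `m = 0 .. M-1`, with
#'   `rho[0] = 1`.
#' @export
triangle_coherence <- function(M) 1 - (0:(M - 1)) / M

#' @rdname triangle_coherence
#' @export
damped_triangle_coherence <- function(M, m0) {
  if (m0 <= 0) stop("m0 must be positive")
  triangle_coherence(M) * exp(-(0:(M - 1)) / m0)
}

#' @rdname triangle_coherence
#' @export
delta_coherence <- function(M) c(1, rep(0, M - 1))

# Factor the Toeplitz channel covariance implied by a coherence profile.
# Negative eigenvalues (profiles that are not positive semidefinite) are
# clipped to zero. Returns the M x M factor L with L %*% Conj(t(L)) = T.
coherence_factor <- function(coherence_profile, M) {
  rho <- coherence_profile
  if (length(rho) < M) stop("coherence profile shorter than channel count")
  rho <- rho[seq_len(M)]
  if (abs(rho[1] - 1) > 1e-9) stop("coherence profile must have rho[0] = 1")
  if (any(abs(rho) > 1 + 1e-9)) stop("coherence values must lie in [-1, 1]")
  Tm <- stats::toeplitz(rho)
  eg <- eigen(Tm, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  if (all(lam <= 0)) stop("coherence profile is not representable")
  # drop numerically-zero modes so degenerate (e.g. rank-1) profiles are exact
  lam[lam < M * .Machine$double.eps * max(lam)] <- 0
  eg$vectors %*% diag(sqrt(lam))
}

# n columns of i.i.d. circular complex standard Gaussians (M x n).
complex_gaussian <- function(M, n) {
  matrix(complex(real = stats::rnorm(M * n), imaginary = stats::rnorm(M * n)) /
           sqrt(2), M, n)
}

#' Draw channel samples with a prescribed spatial-coherence structure
#'
#' Zero-mean circular complex Gaussian samples whose channel covariance
#' equals the Toeplitz matrix `T[i, j] = rho[|i - j|]` (after clipping
#' negative eigenvalues to zero), independent across slow time. This is
#' how the simulator realizes the quantity the coherence estimator
#' measures, without physical wave simulation.
#'
#' @param coherence_profile Numeric vector `rho[m]`, `m = 0 .. M-1`.
#' @param M Number of channels.
#' @param K Number of slow-time samples (independent draws).
#' @param seed Optional integer seed for reproducibility.
#' @return Complex matrix `(channel, slow_time)`.
#' @export
correlated_channel_draw <- function(coherence_profile, M, K, seed = NULL) {
  stopifnot(M >= 1, K >= 1)
  if (!is.null(seed)) set.seed(seed)
  L <- coherence_factor(coherence_profile, M)
  L %*% complex_gaussian(M, K)
}

#' Signal component of a simulated pixel
#'
#' Describes one additive constituent of the slow-time channel signal at a
#' pixel: diffuse `speckle` (stationary), `blood` (a slow-time phase ramp
#' at its Doppler frequency), `clutter` (slowly moving, optionally
#' cyclically modulated and partially decorrelating), or thermal `noise`
#' (redrawn every slow-time sample).
#'
#' @param kind One of `"blood"`, `"clutter"`, `"noise"`, `"speckle"`.
#' @param amplitude Linear amplitude relative to the scene reference.
#' @param doppler_fraction Slow-time frequency as a fraction of the PRF
#'   (0 for stationary); `|doppler_fraction| < 0.5`.
#' @param coherence_profile Channel coherence `rho[m]`; defaults to the
#'   triangle for blood/speckle and to channel-independent for noise.
#' @param slow_time_modulation Optional cyclic frequency in Hz. The
#'   component's Doppler fraction is multiplied by a sinusoid sampled at
#'   the frame times, emulating cyclic bulk motion coupled into a clutter
#'   layer.
#' @param slow_time_ar First-order autoregressive coefficient across slow
#'   time in `(0, 1]`; 1 (default) freezes the channel realization within
#'   the ensemble, smaller values model progressive decorrelation (a
#'   spectral broadening of the component).
#' @return A `component_spec` object.
#' @export
component_spec <- function(kind = c("blood", "clutter", "noise", "speckle"),
                           amplitude = 1, doppler_fraction = 0,
                           coherence_profile = NULL,
                           slow_time_modulation = NULL,
                           slow_time_ar = 1) {
  kind <- match.arg(kind)
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (abs(doppler_fraction) >= 0.5)
    stop("|doppler_fraction| must be below 0.5 (the slow-time Nyquist)")
  if (slow_time_ar <= 0 || slow_time_ar > 1)
    stop("slow_time_ar must lie in (0, 1]")
  structure(list(kind = kind, amplitude = amplitude,
                 doppler_fraction = doppler_fraction,
                 coherence_profile = coherence_profile,
                 slow_time_modulation = slow_time_modulation,
                 slow_time_ar = slow_time_ar),
            class = "component_spec")
}

resolve_profile <- function(component, M) {
  if (!is.null(component$coherence_profile)) return(component$coherence_profile)
  if (component$kind == "noise") delta_coherence(M) else triangle_coherence(M)
}

# Generate one component's contribution for a batch of pixels sharing the
# same component spec (up to per-pixel Doppler fraction).
# L: channel factor; fractions: per-pixel Doppler fraction (length N);
# returns complex array (N, M, K).
component_field <- function(component, L, fractions, M, K, frame_time) {
  N <- length(fractions)
  amp <- component$amplitude
  if (component$kind == "noise") {
    return(array(amp * complex(real = stats::rnorm(N * M * K),
                               imaginary = stats::rnorm(N * M * K)) / sqrt(2),
                 c(N, M, K)))
  }
  ar <- component$slow_time_ar
  g <- array(0i, c(N, M, K))
  g0 <- t(L %*% complex_gaussian(M, N))              # (N, M)
  g[, , 1] <- g0
  if (ar < 1) {
    innov <- sqrt(1 - ar^2)
    for (k in 2:K)
      g[, , k] <- ar * g[, , k - 1] + innov * t(L %*% complex_gaussian(M, N))
  } else if (K > 1) {
    for (k in 2:K) g[, , k] <- g0
  }
  f_eff <- fractions
  if (!is.null(component$slow_time_modulation))
    f_eff <- f_eff * sin(2 * pi * component$slow_time_modulation * frame_time)
  ramp <- exp(2i * pi * outer(f_eff, 0:(K - 1)))     # (N, K)
  g * aperm(array(ramp, c(N, K, M)), c(1, 3, 2)) * amp
}

#' Simulate the channel ensemble of a single pixel
#'
#' Sums the contributions of a list of signal components:
#' `u_i[k] = sum_c a_c g_{c,i}[k] exp(j 2 pi f_c k)`, where `g_{c,i}[k]`
#' is a channel draw with the component's coherence profile, held fixed
#' across slow time for blood/clutter/speckle (unless `slow_time_ar < 1`)
#' and redrawn every sample for noise.
#'
#' @param components List of [component_spec()] objects (non-empty).
#' @param acq An [acq_params()].
#' @param seed Optional integer seed.
#' @param n_frames Number of frames to generate (default `acq$n_frames`).
#' @return A [channel_ensemble()] on a 1 x 1 grid.
#' @export
simulate_pixel <- function(components, acq, seed = NULL,
                           n_frames = acq$n_frames) {
  stopifnot(inherits(acq, "acq_params"), length(components) >= 1,
            all(vapply(components, inherits, logical(1), "component_spec")))
  if (!is.null(seed)) set.seed(seed)
  M <- acq$n_channels; K <- acq$ensemble
  u <- array(0i, c(1, M, K, n_frames))
  for (comp in components) {
    L <- if (comp$kind == "noise") NULL
         else coherence_factor(resolve_profile(comp, M), M)
    for (fr in seq_len(n_frames)) {
      t_fr <- fr / acq$frame_rate
      u[1, , , fr] <- u[1, , , fr] +
        component_field(comp, L, comp$doppler_fraction, M, K, t_fr)[1, , ]
    }
  }
  channel_ensemble(u, image_grid(1, 1), acq)
}

#' Expected measured coherence of a Gaussian channel pair
#'
#' The per-sample normalized correlation estimator applied to a jointly
#' circular Gaussian channel pair with true correlation `rho` has
#' expectation `(pi/4) rho 2F1(1/2, 1/2; 2; rho^2)` -- slightly below
#' `rho` except at 0 and 1. The scene presets invert this relation to
#' calibrate their noise levels so the *measured* lag-one coherence hits
#' a target value.
#'
#' @param rho True channel correlation(s), in `[0, 1)` or 1.
#' @return Expected value(s) of the per-sample normalized correlation.
#' @export
expected_lag_coherence <- function(rho) {
  vapply(rho, function(r) {
    if (r < 0 || r > 1) stop("rho must lie in [0, 1]")
    if (r == 1) return(1)
    z <- r^2; term <- 1; s <- 1
    for (n in 0:2000) {
      term <- term * ((0.5 + n)^2 / ((2 + n) * (n + 1))) * z
      s <- s + term
      if (abs(term) < 1e-14) break
    }
    (pi / 4) * r * s
  }, numeric(1))
}

invert_lag_coherence <- function(target) {
  if (target <= 0 || target >= 1)
    stop("target measured coherence must lie in (0, 1)")
  stats::uniroot(function(r) expected_lag_coherence(r) - target,
                 c(1e-9, 1 - 1e-9), tol = 1e-10)$root
}

#' Declarative synthetic imaging scene
#'
#' Describes a desk-scale flow-phantom scene on a rectangular grid:
#' background speckle, an optional cylindrical vessel (modeled as an
#' axial band; the Doppler angle scales the sensed velocity), an optional
#' clutter overlay spanning the image (an intervening moving tissue
#' layer), thermal noise, and an optional anechoic region containing no
#' speckle. Pixels are generated independently; all estimators here
#' operate per pixel or on kernels of statistically identical pixels.
#'
#' @param n_axial,n_lateral,spacing_mm Grid geometry (see [image_grid()]).
#' @param speckle `list(amplitude, coherence_profile = NULL)` for the
#'   stationary background; `NULL` for none.
#' @param vessel `NULL` or a list with `center_axial_mm`, `diameter_mm`,
#'   `angle_deg` (Doppler angle), `mean_velocity_cms` (cross-section mean
#'   flow speed along the vessel), `profile` (`"plug"` or `"parabolic"`),
#'   `amplitude`, and optionally `coherence_profile`, `slow_time_ar`.
#' @param clutter `NULL` or a list with `amplitude`, `doppler_fraction`,
#'   `modulation_hz` (cyclic bulk-motion frequency; `NULL` for none),
#'   `slow_time_ar`, and either `coherence_profile` or `m0` (decay length
#'   of a damped-triangle profile; `Inf` for fully correlated clutter).
#' @param noise `list(amplitude)`; `NULL` for none.
#' @param anechoic `NULL` or an [roi_rect()] where speckle is absent.
#' @param seed Integer seed; identical scene + seed gives a bit-identical
#'   dataset.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(n_axial = 64, n_lateral = 40, spacing_mm = c(0.4, 0.4),
                       speckle = list(amplitude = 1),
                       vessel = NULL, clutter = NULL,
                       noise = list(amplitude = 0.1),
                       anechoic = NULL, seed = 1) {
  if (!is.null(vessel)) {
    defaults <- list(center_axial_mm = 6, diameter_mm = 4.8, angle_deg = 70,
                     mean_velocity_cms = 5, profile = "plug", amplitude = 1,
                     coherence_profile = NULL, slow_time_ar = 1)
    vessel <- utils::modifyList(defaults, vessel)
    if (vessel$diameter_mm <= 0) stop("vessel diameter must be positive")
    if (!vessel$profile %in% c("plug", "parabolic"))
      stop("vessel profile must be 'plug' or 'parabolic'")
  }
  if (!is.null(clutter)) {
    defaults <- list(amplitude = 1, doppler_fraction = 0.003,
                     modulation_hz = 2, slow_time_ar = 0.9, m0 = 2,
                     coherence_profile = NULL)
    clutter <- utils::modifyList(defaults, clutter)
  }
  structure(list(n_axial = as.integer(n_axial),
                 n_lateral = as.integer(n_lateral),
                 spacing_mm = spacing_mm, speckle = speckle, vessel = vessel,
                 clutter = clutter, noise = noise, anechoic = anechoic,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

scene_grid <- function(scene) {
  image_grid(scene$n_axial, scene$n_lateral, scene$spacing_mm)
}

# Per-pixel mean axial velocity (cm/s) inside the vessel band; NA outside.
vessel_axial_velocity <- function(scene, grid) {
  co <- grid_coordinates(grid)
  v <- rep(NA_real_, nrow(co))
  ves <- scene$vessel
  if (is.null(ves)) return(v)
  r <- ves$diameter_mm / 2
  d <- abs(co$axial_mm - ves$center_axial_mm)
  inside <- d <= r
  flow <- if (ves$profile == "plug") rep(ves$mean_velocity_cms, sum(inside))
          else 2 * ves$mean_velocity_cms * (1 - (d[inside] / r)^2)
  v[inside] <- flow * cos(ves$angle_deg * pi / 180)
  v
}

#' Simulate a full scene into a multi-frame channel-data ensemble
#'
#' Assembles each pixel's signal components from region membership and
#' generates `acq$n_frames` frames. Vessel pixels carry a blood phase ramp
#' whose slow-time frequency follows the local flow profile and Doppler
#' angle; the ramp's sign is chosen so the velocity estimator recovers
#' positive axial velocities as positive. Speckle is frozen across frames;
#' blood, clutter, and noise realizations are independent across frames
#' (frames are many pulse intervals apart).
#'
#' @param scene A [scene_spec()].
#' @param acq An [acq_params()].
#' @return A [channel_ensemble()] with `acq$n_frames` frames. If the
#'   vessel's peak axial velocity exceeds the Nyquist velocity a warning
#'   flags the expected aliasing.
#' @export
simulate_scene <- function(scene, acq) {
  stopifnot(inherits(scene, "scene_spec"), inherits(acq, "acq_params"))
  set.seed(scene$seed)
  grid <- scene_grid(scene)
  M <- acq$n_channels; K <- acq$ensemble; nf <- acq$n_frames
  P <- n_pixels(grid)
  u <- array(0i, c(P, M, K, nf))
  frame_times <- seq_len(nf) / acq$frame_rate

  v_ax <- vessel_axial_velocity(scene, grid)
  vessel_px <- which(!is.na(v_ax))
  anech_px <- if (is.null(scene$anechoic)) integer(0)
              else roi_pixels(scene$anechoic, grid)
  speckle_px <- setdiff(seq_len(P), union(vessel_px, anech_px))

  # stationary background speckle: one frozen realization per pixel
  if (!is.null(scene$speckle) && length(speckle_px) > 0 &&
      scene$speckle$amplitude > 0) {
    prof <- scene$speckle$coherence_profile
    if (is.null(prof)) prof <- triangle_coherence(M)
    L <- coherence_factor(prof, M)
    S <- t(L %*% complex_gaussian(M, length(speckle_px)))    # (N, M)
    contrib <- scene$speckle$amplitude *
      array(S, c(length(speckle_px), M, K))
    for (fr in seq_len(nf)) u[speckle_px, , , fr] <- contrib
  }

  # blood inside the vessel: phase ramp at the local Doppler fraction
  if (length(vessel_px) > 0 && scene$vessel$amplitude > 0) {
    ves <- scene$vessel
    peak <- max(abs(v_ax[vessel_px]))
    if (peak > nyquist_velocity(acq))
      warning("vessel axial velocity exceeds the Nyquist velocity: aliasing expected")
    fd <- suppressWarnings(doppler_shift(v_ax[vessel_px], acq)) / acq$prf
    prof <- ves$coherence_profile
    if (is.null(prof)) prof <- triangle_coherence(M)
    comp <- component_spec("blood", amplitude = ves$amplitude,
                           coherence_profile = prof,
                           slow_time_ar = ves$slow_time_ar)
    L <- coherence_factor(prof, M)
    for (fr in seq_len(nf))
      u[vessel_px, , , fr] <- u[vessel_px, , , fr] +
        component_field(comp, L, -fd, M, K, frame_times[fr])
  }

  # clutter overlay across the whole image (intervening moving tissue)
  if (!is.null(scene$clutter) && scene$clutter$amplitude > 0) {
    cl <- scene$clutter
    prof <- cl$coherence_profile
    if (is.null(prof))
      prof <- if (is.infinite(cl$m0)) triangle_coherence(M)
              else damped_triangle_coherence(M, cl$m0)
    comp <- component_spec("clutter", amplitude = cl$amplitude,
                           doppler_fraction = cl$doppler_fraction,
                           coherence_profile = prof,
                           slow_time_modulation = cl$modulation_hz,
                           slow_time_ar = cl$slow_time_ar)
    L <- coherence_factor(prof, M)
    for (fr in seq_len(nf))
      u[, , , fr] <- u[, , , fr] +
        component_field(comp, L, rep(cl$doppler_fraction, P), M, K,
                        frame_times[fr])
  }

  # thermal noise: independent across everything
  if (!is.null(scene$noise) && scene$noise$amplitude > 0)
    u <- u + scene$noise$amplitude *
      array(complex(real = stats::rnorm(length(u)),
                    imaginary = stats::rnorm(length(u))) / sqrt(2), dim(u))

  out <- channel_ensemble(u, grid, acq)
  attr(out, "scene") <- scene
  out
}

#' Calibrated scene presets
#'
#' Ready-made scenes emulating a Doppler flow phantom (4.8 mm vessel at a
#' 70 degree Doppler angle) imaged through different intervening media:
#'
#' * `water_path` -- clutter-free; noise only.
#' * `tissue1` -- a moderate, weakly-coherent moving clutter layer
#'   (+10 dB power over speckle, damped-triangle coherence, 2 Hz cyclic
#'   motion, mild slow-time decorrelation).
#' * `tissue2` -- a thicker layer: stronger clutter (+16 dB) and much
#'   higher noise.
#' * `correlated_clutter` -- the stress case: strong (+20 dB) clutter with
#'   the *full* triangle coherence of on-axis signal plus high noise,
#'   which defeats coherence feedback and drives the adaptive method to
#'   prefer no filtering inside the vessel.
#'
#' For the first three presets the thermal noise amplitude is solved
#' analytically (via [expected_lag_coherence()]) so that the measured
#' lag-one coherence in a background speckle ROI equals 0.75, 0.45, and
#' 0.36 respectively.
#'
#' @param name Preset name.
#' @param acq Acquisition the calibration should assume (channel count
#'   enters the coherence profiles). Default [default_acq()].
#' @param flow_ml_min Pump flow setting, mL/min; 160 and 320 correspond to
#'   mean axial velocities of about 5 and 10 cm/s at the default geometry.
#' @param n_axial,n_lateral Grid size in pixels (0.4 mm pitch).
#' @param seed Scene seed.
#' @return A [scene_spec()].
#' @export
scene_presets <- function(name = c("water_path", "tissue1", "tissue2",
                                   "correlated_clutter"),
                          acq = default_acq(), flow_ml_min = 160,
                          n_axial = 64, n_lateral = 40, seed = 1) {
  name <- match.arg(name)
  M <- acq$n_channels
  rho_s1 <- 1 - 1 / M
  v_mean <- mean_axial_velocity_from_flow(flow_ml_min, 4.8, 70) /
    cos(70 * pi / 180)  # flow speed along the vessel; angle applied per pixel
  vessel <- list(center_axial_mm = 6, diameter_mm = 4.8, angle_deg = 70,
                 mean_velocity_cms = v_mean, profile = "plug", amplitude = 1)
  loc_targets <- c(water_path = 0.75, tissue1 = 0.45, tissue2 = 0.36)

  clutter <- switch(name,
    water_path = NULL,
    tissue1 = list(amplitude = sqrt(10), doppler_fraction = 0.003,
                   modulation_hz = 2, slow_time_ar = 0.9, m0 = 2),
    tissue2 = list(amplitude = sqrt(40), doppler_fraction = 0.003,
                   modulation_hz = 2, slow_time_ar = 0.9, m0 = 2),
    correlated_clutter = list(amplitude = 10, doppler_fraction = 0.002,
                              modulation_hz = NULL, slow_time_ar = 0.98,
                              m0 = Inf))

  if (name %in% names(loc_targets)) {
    # solve the noise power so the measured background LOC hits its target
    rho_c1 <- if (is.null(clutter)) 0
              else (1 - 1 / M) * exp(-1 / clutter$m0)
    p_c <- if (is.null(clutter)) 0 else clutter$amplitude^2
    rho_target <- invert_lag_coherence(loc_targets[[name]])
    p_n <- (rho_s1 + p_c * rho_c1) / rho_target - (1 + p_c)
    if (p_n <= 0)
      stop("preset not calibratable: clutter too incoherent for target LOC")
    noise <- list(amplitude = sqrt(p_n))
  } else {
    noise <- list(amplitude = sqrt(2))
  }

  scene_spec(n_axial = n_axial, n_lateral = n_lateral,
             speckle = list(amplitude = 1), vessel = vessel,
             clutter = clutter, noise = noise, seed = seed)
}

#' Background speckle ROI of a preset scene
#'
#' The rectangle of stationary background speckle beneath the vessel,
#' used for lag-one coherence measurements.
#'
#' @param scene A [scene_spec()] with a vessel.
#' @return An [roi_rect()].
#' @export
speckle_roi <- function(scene) {
  grid <- scene_grid(scene)
  top <- scene$vessel$center_axial_mm + scene$vessel$diameter_mm / 2 +
    2 * scene$spacing_mm[1]
  roi_rect(axial_mm = c(top, (scene$n_axial - 1) * scene$spacing_mm[1]),
           lateral_mm = c(0, (scene$n_lateral - 1) * scene$spacing_mm[2]))
}

#' Vessel ROI of a scene
#'
#' The axial band spanned by the vessel across the full lateral extent.
#'
#' @param scene A [scene_spec()] with a vessel.
#' @param margin_mm Shrink the band by this much on each side to avoid
#'   boundary pixels. Default 0.
#' @return An [roi_rect()].
#' @export
vessel_roi <- function(scene, margin_mm = 0) {
  if (is.null(scene$vessel)) stop("scene has no vessel")
  r <- scene$vessel$diameter_mm / 2 - margin_mm
  roi_rect(axial_mm = scene$vessel$center_axial_mm + c(-r, r),
           lateral_mm = c(0, (scene$n_lateral - 1) * scene$spacing_mm[2]))
}
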