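test_that("correlated draws realize the prescribed channel covariance", {
  # rank-1 profile: all channels identical
  x <- correlated_channel_draw(rep(1, 8), 8, 5, seed = 1)
  expect_lt(max(Mod(sweep(x, 2, x[1, ], `-`))), 1e-10)
  # channel-independent profile: off-diagonal sample covariance vanishes
  x <- correlated_channel_draw(delta_coherence(16), 16, 4000, seed = 2)
  S <- (x %*% Conj(t(x))) / 4000
  expect_lt(max(Mod(S - diag(diag(Re(S))))), 0.1)
  # triangle profile, M = 64: entrywise covariance recovery
  M <- 64
  x <- correlated_channel_draw(triangle_coherence(M), M, 1e4, seed = 5)
  S <- (x %*% Conj(t(x))) / 1e4
  expect_lt(max(Mod(S - stats::toeplitz(triangle_coherence(M)))), 0.03)
})

test_that("invalid coherence profiles are rejected", {
  expect_error(correlated_channel_draw(c(0.5, 0.2), 2, 3), "rho\\[0\\]")
  expect_error(correlated_channel_draw(c(1, 2), 2, 3), "\\[-1, 1\\]")
  expect_error(component_spec("blood", amplitude = -1), "non-negative")
  expect_error(component_spec("blood", doppler_fraction = 0.6), "Nyquist")
})

test_that("a fully coherent blood component is a pure slow-time phase ramp", {
  acq <- acq_params(3.5e6, 3000, n_channels = 8, ensemble = 10)
  comp <- component_spec("blood", amplitude = 1, doppler_fraction = 0.1,
                         coherence_profile = rep(1, 8))
  px <- simulate_pixel(list(comp), acq, seed = 3)
  u <- px$data[1, , , 1]
  # all channels identical
  expect_lt(max(Mod(sweep(u, 2, u[1, ], `-`))), 1e-10)
  # consecutive-sample ratio is the prescribed phasor
  ratios <- u[1, 2:10] / u[1, 1:9]
  expect_lt(max(Mod(ratios - exp(2i * pi * 0.1))), 1e-10)
  # unit modulus up to the random initial phase magnitude
  expect_lt(max(abs(Mod(u) - Mod(u[1, 1]))), 1e-10)
})

test_that("noise components are uncorrelated across channels and slow time", {
  acq <- acq_params(3.5e6, 3000, n_channels = 16, ensemble = 12)
  comp <- component_spec("noise", amplitude = 1)
  set.seed(10)
  draws <- replicate(400, {
    u <- simulate_pixel(list(comp), acq)$data[1, , , 1]
    c(u[1, 1] * Conj(u[2, 1]), u[1, 1] * Conj(u[1, 2]))
  })
  expect_lt(Mod(mean(draws[1, ])), 3 / sqrt(400))
  expect_lt(Mod(mean(draws[2, ])), 3 / sqrt(400))
})

test_that("a strong slow clutter component dominates the beamsum spectrum", {
  acq <- acq_params(3.5e6, 3000, n_channels = 16, ensemble = 14)
  blood <- component_spec("blood", amplitude = 1, doppler_fraction = 0.1,
                          coherence_profile = triangle_coherence(16))
  clutter <- component_spec("clutter", amplitude = 10,
                            doppler_fraction = 0.005,
                            coherence_profile = triangle_coherence(16))
  px <- simulate_pixel(list(blood, clutter), acq, seed = 4)
  U <- colSums(px$data[1, , , 1])
  freqs <- (0:13) / 14
  pgram <- Mod(vapply(freqs, function(f)
    sum(U * exp(-2i * pi * f * (0:13))), complex(1)))^2
  peak <- freqs[which.max(pgram)]
  # dominant peak at (or wrapped next to) the clutter frequency, not 0.1
  expect_lt(min(abs(peak - 0.005), abs(peak - 1 + 0.005)), 1.5 / 14)
})

test_that("scene generation is deterministic given its seed", {
  acq <- acq_params(3.5e6, 3000, n_channels = 8, ensemble = 6, n_frames = 2)
  sc <- scene_spec(n_axial = 8, n_lateral = 4,
                   vessel = list(center_axial_mm = 1, diameter_mm = 1.2),
                   clutter = list(amplitude = 2), seed = 99)
  d1 <- simulate_scene(sc, acq)
  d2 <- simulate_scene(sc, acq)
  expect_identical(d1$data, d2$data)
})

test_that("doubling a component amplitude quadruples its beamsum power", {
  acq <- acq_params(3.5e6, 3000, n_channels = 16, ensemble = 14)
  pw <- function(amp) {
    sc <- scene_spec(n_axial = 20, n_lateral = 20,
                     speckle = list(amplitude = amp), noise = NULL, seed = 7)
    bs <- beamsum(simulate_scene(sc, acq))
    mean(Mod(bs$data)^2)
  }
  expect_equal(pw(2) / pw(1), 4, tolerance = 1e-9)  # same seed, exact scaling
})

test_that("measured coherence of generated speckle matches its expectation", {
  # the per-sample-normalized estimator has expectation below the true
  # channel correlation; compare against the analytic expectation
  acq <- default_acq()
  prof <- damped_triangle_coherence(64, 5)
  sc <- scene_spec(n_axial = 40, n_lateral = 30,
                   speckle = list(amplitude = 1, coherence_profile = prof),
                   noise = NULL, seed = 4)
  ds <- simulate_scene(sc, acq)
  P <- 1200
  measured <- vapply(1:10, function(m) {
    mean(vapply(seq_len(P), function(p)
      Re(correlation_profile(ds$data[p, , , 1])[m]), numeric(1)))
  }, numeric(1))
  expect_lt(max(abs(measured - expected_lag_coherence(prof[2:11]))), 0.02)
})

test_that("a stationary speckle scene yields near-zero unfiltered velocities", {
  acq <- acq_params(3.5e6, 3000, n_channels = 32, ensemble = 14)
  sc <- scene_spec(n_axial = 15, n_lateral = 15, noise = NULL, seed = 5)
  vm <- velocity_map(beamsum(simulate_scene(sc, acq)))
  expect_lt(max(abs(vm$v_hat)), 1e-6)
})

test_that("unfiltered velocity recovery in a clean vessel is within 5%", {
  acq <- default_acq()
  sc <- scene_presets("water_path", flow_ml_min = 160, n_axial = 32,
                      n_lateral = 20, seed = 21)
  sc$noise <- NULL  # clean phase ramp
  ds <- simulate_scene(sc, acq)
  rv <- vessel_roi(sc, margin_mm = 0.4)
  vm <- velocity_map(beamsum(ds))
  v_in <- mean(vm$v_hat[roi_pixels(rv, ds$grid), 1])
  expect_equal(v_in, 5.04, tolerance = 0.05 * 5.04)
})

test_that("super-Nyquist vessel velocities raise an aliasing warning", {
  acq <- acq_params(3.5e6, 3000, n_channels = 8, ensemble = 6)
  sc <- scene_spec(n_axial = 10, n_lateral = 4,
                   vessel = list(center_axial_mm = 2, diameter_mm = 2,
                                 mean_velocity_cms = 150, angle_deg = 30),
                   seed = 1)
  expect_warning(simulate_scene(sc, acq), "alias")
})

test_that("preset noise calibration is solved, not hard-coded", {
  # water path: noise power satisfies the lag-one calibration equation
  sc <- scene_presets("water_path")
  rho_eff <- (1 - 1 / 64) / (1 + sc$noise$amplitude^2)
  expect_equal(expected_lag_coherence(rho_eff), 0.75, tolerance = 1e-6)
  sc1 <- scene_presets("tissue1")
  p_c <- sc1$clutter$amplitude^2
  rho_c1 <- (1 - 1 / 64) * exp(-1 / sc1$clutter$m0)
  rho_eff1 <- ((1 - 1 / 64) + p_c * rho_c1) /
    (1 + p_c + sc1$noise$amplitude^2)
  expect_equal(expected_lag_coherence(rho_eff1), 0.45, tolerance = 1e-6)
  expect_error(scene_presets("nope"), "arg")
})
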