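make_vmap <- function(v, grid, acq, mask = NULL) {
  structure(list(v_hat = matrix(v, ncol = 1),
                 phi_hat = matrix(0, length(v), 1),
                 mask = if (is.null(mask)) matrix(FALSE, length(v), 1) else mask,
                 grid = grid, acq = acq),
            class = "velocity_map")
}

test_that("variance thresholding rejects by the population kernel variance", {
  acq <- acq_params(3.5e6, 3000, n_channels = 4, ensemble = 4)
  g <- image_grid(2, 2, spacing_mm = c(1, 1))
  # kernel spans all four pixels; values in mm/s: {0, 0, 0, 10}
  v_cms <- c(0, 0, 0, 1)                        # 1 cm/s = 10 mm/s
  vmap <- make_vmap(v_cms, g, acq)
  # population variance = 18.75 (mm/s)^2: rejected at sigma = 3, kept at 5
  enc3 <- variance_encode(vmap, priority_config(variance_threshold = 3,
                                                kernel_mm = c(3, 3)))
  expect_true(all(enc3$mask))
  expect_true(all(enc3$v_hat == 0))
  enc5 <- variance_encode(vmap, priority_config(variance_threshold = 5,
                                                kernel_mm = c(3, 3)))
  expect_false(any(enc5$mask))
  expect_equal(enc5$v_hat, vmap$v_hat)
  # spatially constant map passes any positive threshold
  const <- make_vmap(rep(2, 4), g, acq)
  encc <- variance_encode(const, priority_config(variance_threshold = 0.1,
                                                 kernel_mm = c(3, 3)))
  expect_false(any(encc$mask))
  # disabled threshold is the identity
  expect_identical(variance_encode(vmap, priority_config()), vmap)
})

test_that("power thresholding normalizes to the image-max pixel power", {
  acq <- acq_params(3.5e6, 3000, n_channels = 4, ensemble = 4)
  g <- image_grid(3, 3, spacing_mm = c(10, 10))  # kernels are single-pixel
  amp <- c(1, 1, 1, 1, 10, 1, 0, 1, 1)           # pixel 5 strongest, 7 silent
  U <- array(0i, c(9, 4, 1))
  for (p in 1:9) U[p, , 1] <- amp[p]
  beams <- beam_ensemble(U, g, acq)
  vmap <- make_vmap(rep(1, 9), g, acq)
  enc <- power_encode(vmap, beams, priority_config(power_threshold = -10,
                                                   kernel_mm = c(1, 1)))
  expect_false(enc$mask[5, 1])                  # the max pixel always stays
  expect_true(enc$mask[7, 1])                   # -Inf dB is always rejected
  expect_true(enc$mask[1, 1])                   # -20 dB < -10 dB
  # uniform power: everything at 0 dB is retained at P = -10
  U1 <- array(1 + 0i, c(9, 4, 1))
  enc_u <- power_encode(vmap, beam_ensemble(U1, g, acq),
                        priority_config(power_threshold = -10,
                                        kernel_mm = c(1, 1)))
  expect_false(any(enc_u$mask))
  # all-zero image rejects everything, with a warning
  U0 <- array(0i, c(9, 4, 1))
  expect_warning(
    enc0 <- power_encode(vmap, beam_ensemble(U0, g, acq),
                         priority_config(power_threshold = -30)),
    "all-zero")
  expect_true(all(enc0$mask))
})

test_that("encoding only masks pixels, never alters retained values", {
  set.seed(51)
  acq <- acq_params(3.5e6, 3000, n_channels = 4, ensemble = 6)
  g <- image_grid(8, 8, spacing_mm = c(1, 1))
  U <- array(complex(real = rnorm(64 * 6), imaginary = rnorm(64 * 6)),
             c(64, 6, 1))
  beams <- beam_ensemble(U, g, acq)
  vmap <- velocity_map(beams)
  cfg <- priority_config(variance_threshold = 5, power_threshold = -6,
                         kernel_mm = c(2, 2))
  enc <- power_encode(variance_encode(vmap, cfg), beams, cfg)
  kept <- !enc$mask
  expect_identical(enc$v_hat[kept], vmap$v_hat[kept])
  expect_true(all(enc$v_hat[enc$mask] == 0))
})

test_that("retained sets shrink monotonically with the thresholds", {
  set.seed(52)
  acq <- acq_params(3.5e6, 3000, n_channels = 4, ensemble = 6)
  g <- image_grid(10, 10, spacing_mm = c(1, 1))
  U <- array(complex(real = rnorm(600), imaginary = rnorm(600)), c(100, 6, 1))
  beams <- beam_ensemble(U, g, acq)
  vmap <- velocity_map(beams)
  kept_at <- function(sigma, p_db) {
    cfg <- priority_config(variance_threshold = sigma, power_threshold = p_db,
                           kernel_mm = c(2, 2))
    !power_encode(variance_encode(vmap, cfg), beams, cfg)$mask[, 1]
  }
  base <- kept_at(3, -35)
  for (p_db in c(-25, -15, -10)) {
    cur <- kept_at(3, p_db)
    expect_true(all(base | !cur))               # cur subset of base
    base <- cur
  }
  base <- kept_at(3, -35)
  for (sigma in c(1, 0.3, 0.1)) {
    cur <- kept_at(sigma, -35)
    expect_true(all(base | !cur))
    base <- cur
  }
})

test_that("variance-then-power equals power-then-variance", {
  set.seed(53)
  acq <- acq_params(3.5e6, 3000, n_channels = 4, ensemble = 6)
  g <- image_grid(9, 7, spacing_mm = c(1, 1))
  U <- array(complex(real = rnorm(63 * 6), imaginary = rnorm(63 * 6)),
             c(63, 6, 1))
  beams <- beam_ensemble(U, g, acq)
  vmap <- velocity_map(beams)
  cfg <- priority_config(variance_threshold = 8, power_threshold = -8,
                         kernel_mm = c(2, 2))
  a <- power_encode(variance_encode(vmap, cfg), beams, cfg)
  b <- variance_encode(power_encode(vmap, beams, cfg), cfg)
  expect_identical(a$mask, b$mask)
  expect_identical(a$v_hat, b$v_hat)
})

test_that("priority_sweep composes the two encoders over the grid", {
  set.seed(54)
  acq <- acq_params(3.5e6, 3000, n_channels = 4, ensemble = 6)
  g <- image_grid(10, 6, spacing_mm = c(1, 1))
  U <- array(complex(real = rnorm(60 * 6), imaginary = rnorm(60 * 6)),
             c(60, 6, 1))
  beams <- beam_ensemble(U, g, acq)
  vmap <- velocity_map(beams)
  roi_a <- roi_rect(c(0, 4), c(0, 5))
  roi_b <- roi_rect(c(5, 9), c(0, 5))
  sw <- priority_sweep(vmap, beams, sigma_list = 2, power_list = -8,
                       roi_in = roi_a, roi_out = roi_b, kernel_mm = c(2, 2))
  cfg <- priority_config(variance_threshold = 2, power_threshold = -8,
                         kernel_mm = c(2, 2))
  direct <- power_encode(variance_encode(vmap, cfg), beams, cfg)
  expect_identical(sw$maps[[1]][[1]]$v_hat, direct$v_hat)
  expect_equal(nrow(sw$summary), 2)
  expect_setequal(sw$summary$roi, c("in", "out"))
})
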