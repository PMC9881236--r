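test_that("ROI statistics use population normalization and spatial stderr", {
  acq <- acq_params(3.5e6, 3000, n_channels = 4, ensemble = 4)
  g <- image_grid(2, 2, spacing_mm = c(1, 1))
  vmap <- structure(list(v_hat = matrix(c(1, 2, 3, 4), 4, 1),
                         phi_hat = matrix(0, 4, 1),
                         mask = matrix(FALSE, 4, 1), grid = g, acq = acq),
                    class = "velocity_map")
  st <- roi_stats(vmap, 1:4)
  expect_equal(st$mean, 2.5)
  expect_equal(st$sd, sqrt(mean((c(1, 2, 3, 4) - 2.5)^2)))
  expect_equal(st$sd, 1.118, tolerance = 1e-3)
  expect_equal(st$stderr, st$sd / 2)
  expect_equal(st$n, 4L)
  # constant map
  vmap$v_hat[] <- 7
  stc <- roi_stats(vmap, 1:4)
  expect_equal(stc$mean, 7)
  expect_equal(stc$sd, 0)
  # two identical frames give identical summaries
  vmap2 <- vmap
  vmap2$v_hat <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  vmap2$mask <- matrix(FALSE, 4, 2)
  st2 <- roi_stats(vmap2, 1:4)
  expect_equal(st2$mean[1], st2$mean[2])
  expect_equal(st2$sd[1], st2$sd[2])
  # rejected pixels are excluded and counted
  vmap3 <- vmap2
  vmap3$mask[1, 1] <- TRUE
  vmap3$v_hat[1, 1] <- 0
  st3 <- roi_stats(vmap3, 1:4, frames = 1)
  expect_equal(st3$n, 3L)
  expect_equal(st3$n_rejected, 1L)
  expect_equal(st3$mean, 3)
})

test_that("contrast follows the 20 log10 amplitude convention", {
  g <- image_grid(4, 2, spacing_mm = c(1, 1))
  env <- c(rep(1, 4), rep(0.2, 4))
  roi_a <- 5:8; roi_b <- 1:4
  expect_equal(contrast_db(env, roi_b, roi_b, g), 0)
  expect_equal(contrast_db(c(rep(0.1, 4), rep(1, 4)), 1:4, 5:8, g), -20)
  expect_equal(contrast_db(env, roi_a, roi_b, g), 20 * log10(0.2))
  expect_equal(contrast_db(env, roi_a, roi_b, g), -13.98, tolerance = 1e-2)
  expect_error(contrast_db(c(rep(1, 4), rep(0, 4)), 1:4, 5:8, g), "zero")
})

test_that("the cost model reproduces the expected slowdown", {
  expect_equal(round(flop_ratio(flop_model(64, 14, 8)) / 10) * 10, 520)
  expect_equal(flop_ratio(flop_model(1, 1, 1)), 1.5)
  r <- vapply(1:6, function(F) flop_ratio(flop_model(64, 14, F)), numeric(1))
  expect_true(all(diff(r) > 0))
  # the asymptotic model tracks a structural count of the implementation
  cnt <- instrumented_flop_count(64, 14, 8)
  model <- flop_ratio(flop_model(64, 14, 8))
  expect_lt(max(cnt$ratio / model, model / cnt$ratio), 2)
})

test_that("acquisition duration is frames over rate", {
  expect_equal(round(acquisition_duration(20, 12), 1), 1.7)
  expect_equal(acquisition_duration(0, 10), 0)
  expect_equal(acquisition_duration(12, 12), 1)
})

test_that("the HDF5 container round-trips channel data bit-exactly", {
  acq <- acq_params(3.5e6, 3000, n_channels = 6, ensemble = 8, n_frames = 2)
  sc <- scene_spec(n_axial = 6, n_lateral = 4,
                   vessel = list(center_axial_mm = 1, diameter_mm = 1),
                   clutter = list(amplitude = 3), seed = 71)
  ds <- simulate_scene(sc, acq)
  path <- tempfile(fileext = ".h5")
  on.exit(unlink(path))
  write_channel_container(ds, path)
  back <- read_channel_container(path)
  expect_identical(back$data, ds$data)
  expect_equal(back$acq, ds$acq)
  expect_equal(back$grid, ds$grid)
  # provenance survives and regenerates the identical dataset
  sc_back <- attr(back, "scene")
  expect_s3_class(sc_back, "scene_spec")
  expect_identical(simulate_scene(sc_back, acq)$data, ds$data)
})

test_that("containers with missing or foreign metadata are rejected", {
  path <- tempfile(fileext = ".h5")
  on.exit(unlink(path))
  rhdf5::h5createFile(path)
  rhdf5::h5write(1:3, path, "junk")
  rhdf5::h5closeAll()
  expect_error(read_channel_container(path), "container_version")
  expect_error(read_channel_container(tempfile()), "no such file")
})

test_that("a reloaded container reproduces identical adaptive output", {
  acq <- acq_params(3.5e6, 3000, n_channels = 8, ensemble = 14)
  sc <- scene_spec(n_axial = 8, n_lateral = 6,
                   vessel = list(center_axial_mm = 1.2, diameter_mm = 1.6),
                   noise = list(amplitude = 0.3), seed = 72)
  ds <- simulate_scene(sc, acq)
  path <- tempfile(fileext = ".h5")
  on.exit(unlink(path))
  write_channel_container(ds, path)
  back <- read_channel_container(path)
  bank <- clutter_filter_bank(list(identity_filter(), design_highpass(0.1)))
  img1 <- cacf_image(ds, bank, q = 5)
  img2 <- cacf_image(back, bank, q = 5)
  expect_identical(img1$velocity, img2$velocity)
  expect_identical(img1$selection$index, img2$selection$index)
})

test_that("scene YAML round-trips and bank YAML builds the described bank", {
  sc <- scene_spec(n_axial = 12, n_lateral = 7,
                   vessel = list(center_axial_mm = 2, diameter_mm = 1.5,
                                 mean_velocity_cms = 8),
                   clutter = list(amplitude = 2, m0 = 3),
                   anechoic = roi_rect(c(4, 5), c(0, 2)), seed = 5)
  sc2 <- scene_from_yaml(scene_to_yaml(sc))
  expect_equal(sc2$vessel$mean_velocity_cms, 8)
  expect_equal(sc2$clutter$m0, 3)
  expect_equal(sc2$anechoic$axial_mm, c(4, 5))
  expect_equal(sc2$seed, 5L)

  bank_file <- tempfile(fileext = ".yaml")
  on.exit(unlink(bank_file))
  writeLines(yaml::as.yaml(list(cutoffs = c(0, 0.05, 0.2), order = 3)),
             bank_file)
  bank <- read_bank_yaml(bank_file)
  expect_length(bank, 3)
  expect_equal(bank_cutoffs(bank), c(0, 0.05, 0.2))
  expect_equal(bank[[2]]$order, 3L)
})

test_that("image containers store velocity and selection grids", {
  ds <- random_ensemble(6, 8, 14, seed = 73)
  bank <- clutter_filter_bank(list(identity_filter(), design_highpass(0.1)))
  img <- cacf_image(ds, bank, q = 5)
  path <- tempfile(fileext = ".h5")
  on.exit(unlink(path))
  write_image_container(img, path)
  expect_equal(as.vector(rhdf5::h5read(path, "velocity_cms")),
               as.vector(img$velocity))
  expect_equal(as.vector(rhdf5::h5read(path, "filter_index")),
               as.vector(img$selection$index))
  rhdf5::h5closeAll()
})
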