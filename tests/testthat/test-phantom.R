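test_that("a 0.5 mL tube at 7.46 MBq reports exactly that ground truth", {
  spec <- phantom_tube(7.46)
  ras <- rasterize_phantom(spec)
  expect_equal(sum(ras$true_activity_MBq), 7.46, tolerance = 1e-9)
  expect_equal(ras$total_activity_MBq, 7.46, tolerance = 1e-9)
  ## nominal concentration 14.92 MBq/mL up to support voxelization
  conc <- max(ras$activity$values)
  expect_equal(conc, 14.92, tolerance = 0.15)
  expect_equal(ras$truth_masks[[1]]$provenance, "phantom-truth")
})

test_that("an empty shape list yields zero activity and an all-air CT", {
  g <- grid3(c(8, 8, 8), 1)
  ras <- rasterize_phantom(phantom_spec(list(), g, grid3(c(10, 10, 10), 0.8)))
  expect_true(all(ras$activity$values == 0))
  expect_true(all(ras$ct$values == -1000))
  expect_length(ras$truth_masks, 0)
})

test_that("voxelized sphere volume matches 4/3 pi r^3 within a voxel shell", {
  g <- grid3(c(16, 16, 16), 1)
  spec <- phantom_spec(list(shape_ellipsoid(semiaxes_mm = c(5, 5, 5),
                                            activity_MBq_per_mL = 1)),
                       g, grid3(c(16, 16, 16), 1))
  ras <- rasterize_phantom(spec)
  vol_mL <- mask_volume_mL(ras$truth_masks[[1]])
  analytic <- 4 / 3 * pi * 125 / 1000
  shell <- 4 * pi * 25 * 1 / 1000  # one-voxel surface shell
  expect_lt(abs(vol_mL - analytic), shell)
})

test_that("shapes escaping the grid raise a geometry error naming them", {
  g <- grid3(c(8, 8, 8), 1)
  spec <- phantom_spec(list(
    shape_cylinder(radius_mm = 2, height_mm = 4, activity_MBq_per_mL = 1),
    shape_ellipsoid(center = c(6, 0, 0), semiaxes_mm = c(3, 3, 3))),
    g, grid3(c(8, 8, 8), 1))
  expect_error(rasterize_phantom(spec), "shape 2")
})

test_that("painting order lets later shapes overwrite earlier ones", {
  g <- grid3(c(10, 10, 10), 1)
  spec <- phantom_spec(list(
    shape_ellipsoid(semiaxes_mm = c(4, 4, 4), activity_MBq_per_mL = 1,
                    hu = 0),
    shape_ellipsoid(semiaxes_mm = c(2, 2, 2), activity_MBq_per_mL = 5,
                    hu = 100)),
    g, grid3(c(10, 10, 10), 1))
  ras <- rasterize_phantom(spec)
  center <- ras$activity$values[6, 6, 6]
  expect_equal(center, 5)
  ## outer shape truth counts only the voxels it still owns
  owned <- sum(ras$truth_masks[[1]]$values) - sum(ras$truth_masks[[2]]$values)
  expect_equal(ras$true_activity_MBq[1], owned * 1e-3, tolerance = 1e-12)
})

test_that("with all degradations off each peak window is sensitivity x branching x activity", {
  spec <- tiny_tube(2)
  ras <- rasterize_phantom(spec)
  ct_air <- scalar_image(array(-1000, dim(ras$activity$values)),
                         ras$activity$spacing, ras$activity$origin, "HU")
  cfg <- simulation_config(psf_fwhm_mm = 0, scatter_fraction = 0,
                           noise = "none")
  w <- simulate_windows(ras$activity, ct_air, cfg)
  a_vox <- ras$activity$values * voxel_volume_mL(ras$activity)
  expect_equal(w$peak1_img$values, 2110 * 0.9061 * a_vox, tolerance = 1e-12)
  expect_equal(w$peak2_img$values, 2110 * 0.9412 * a_vox, tolerance = 1e-12)
  expect_true(all(w$scatter_img$values == 0))
})

test_that("simulation is bit-reproducible under a fixed seed", {
  spec <- tiny_tube(1)
  ras <- rasterize_phantom(spec)
  cfg <- simulation_config(seed = 42)
  w1 <- simulate_windows(ras$activity, ras$ct, cfg)
  w2 <- simulate_windows(ras$activity, ras$ct, cfg)
  expect_identical(w1$peak1_img$values, w2$peak1_img$values)
  expect_identical(w1$scatter_img$values, w2$scatter_img$values)
  w3 <- simulate_windows(ras$activity, ras$ct,
                         simulation_config(seed = 43))
  expect_false(identical(w1$peak1_img$values, w3$peak1_img$values))
})

test_that("simulation does not disturb the caller's RNG stream", {
  spec <- tiny_tube(1)
  ras <- rasterize_phantom(spec)
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulate_windows(ras$activity, ras$ct,
                             simulation_config(seed = 5)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("scatter-window counts grow strictly with the scatter fraction", {
  spec <- tiny_tube(2)
  ras <- rasterize_phantom(spec)
  totals <- vapply(c(0, 0.1, 0.2, 0.35), function(sf) {
    cfg <- simulation_config(scatter_fraction = sf, noise = "none")
    sum(simulate_windows(ras$activity, ras$ct, cfg)$scatter_img$values)
  }, numeric(1))
  expect_equal(totals[1], 0)
  expect_true(all(diff(totals) > 0))
})

test_that("Poisson window means match the noise-free expectation", {
  spec <- tiny_tube(2)
  ras <- rasterize_phantom(spec)
  cfg0 <- simulation_config(noise = "none")
  w0 <- simulate_windows(ras$activity, ras$ct, cfg0)
  truth <- attr(w0, "truth")
  n_rep <- 150L
  tot <- matrix(NA_real_, n_rep, 3L)
  for (r in seq_len(n_rep)) {
    cfg <- simulation_config(seed = 1000L + r)
    w <- simulate_windows(ras$activity, ras$ct, cfg)
    tot[r, ] <- c(sum(w$peak1_img$values), sum(w$scatter_img$values),
                  sum(w$peak2_img$values))
  }
  expected <- c(sum(truth$expected_peak1$values),
                sum(truth$expected_scatter$values),
                sum(truth$expected_peak2$values))
  for (j in 1:3) {
    se <- stats::sd(tot[, j]) / sqrt(n_rep)
    expect_lt(abs(mean(tot[, j]) - expected[j]), 3 * se + 1e-12)
  }
})

test_that("phantom and simulation configurations roundtrip through YAML", {
  dir <- withr::local_tempdir()
  spec <- phantom_kidney(3)
  f <- file.path(dir, "kidney.yaml")
  write_phantom_spec(spec, f)
  back <- read_phantom_spec(f)
  expect_equal(rasterize_phantom(back)$total_activity_MBq,
               rasterize_phantom(spec)$total_activity_MBq,
               tolerance = 1e-6)  # YAML prints finite precision
  cfg <- simulation_config(seed = 9, scatter_fraction = 0.15,
                           psf_fwhm_error_fraction = 0.2)
  g <- file.path(dir, "sim.yaml")
  write_simulation_config(cfg, g)
  expect_equal(read_simulation_config(g), cfg)
})

test_that("simulation configuration rejects unphysical settings", {
  expect_error(simulation_config(scatter_fraction = 1), "\\[0, 1\\)")
  expect_error(simulation_config(photopeaks = data.frame(
    energy_keV = 171.3, branching = 0.9)), "two photopeaks")
  expect_error(simulation_config(photopeaks = data.frame(
    energy_keV = c(171.3, 245.4), branching = c(0, 0.9))), "branching")
})
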