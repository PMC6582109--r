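mk_img <- function(vals, dim = c(2, 2, 2), unit = "cps") {
  scalar_image(array(vals, dim), c(1, 1, 1), unit = unit)
}

test_that("DEW subtraction follows the width-ratio / split arithmetic", {
  w <- windowed_counts(mk_img(100), mk_img(30), mk_img(80))
  out <- dew_scatter_correct(w)
  ## widths: peak1 2*0.1*171.3 = 34.26 keV, scatter 2*0.1*209 = 41.8 keV
  expect_equal(out$peak1$values[1, 1, 1], 100 - 0.5 * (34.26 / 41.8) * 30,
               tolerance = 1e-12)
  expect_equal(out$peak2$values[1, 1, 1],
               80 - 0.5 * (2 * 0.1 * 245.4 / 41.8) * 30, tolerance = 1e-12)
})

test_that("DEW with a zero scatter window leaves the peaks unchanged", {
  w <- windowed_counts(mk_img(100), mk_img(0), mk_img(80))
  out <- dew_scatter_correct(w)
  expect_equal(out$peak1$values, w$peak1_img$values)
  expect_equal(out$peak2$values, w$peak2_img$values)
})

test_that("DEW clips to zero instead of going negative, and counts clips", {
  w <- windowed_counts(mk_img(1), mk_img(1000), mk_img(1))
  out <- dew_scatter_correct(w)
  expect_true(all(out$peak1$values == 0))
  expect_equal(attr(out$peak1, "n_clipped"), 8)
})

test_that("DEW is linear in its inputs and never negative", {
  set.seed(31)
  p1 <- mk_img(runif(27, 0, 100), c(3, 3, 3))
  sc <- mk_img(runif(27, 0, 20), c(3, 3, 3))
  p2 <- mk_img(runif(27, 0, 100), c(3, 3, 3))
  out1 <- dew_scatter_correct(windowed_counts(p1, sc, p2))
  out3 <- dew_scatter_correct(windowed_counts(
    mk_img(3 * p1$values, c(3, 3, 3)), mk_img(3 * sc$values, c(3, 3, 3)),
    mk_img(3 * p2$values, c(3, 3, 3))))
  expect_equal(out3$peak1$values, 3 * out1$peak1$values, tolerance = 1e-12)
  expect_true(all(out1$peak1$values >= 0))
  expect_true(all(out1$peak2$values >= 0))
})

test_that("bilinear HU-to-mu hits its anchors and interpolates bone", {
  model <- attenuation_model()
  ct <- mk_img(c(0, -1000, 500, -500, 1000, 2000, 250, -250),
               dim = c(8, 1, 1), unit = "HU")
  mu <- hu_to_mu(ct, 171.3, model)
  expect_equal(mu$unit, "per_mm")
  expect_equal(mu$values[1, 1, 1], 0.0146)                 # water
  expect_equal(mu$values[2, 1, 1], 0)                      # air
  expect_equal(mu$values[3, 1, 1], (0.0146 + 0.0270) / 2)  # half-way to bone
  expect_equal(mu$values[4, 1, 1], 0.0146 * 0.5)           # lung-like
  expect_equal(mu$values[5, 1, 1], 0.0270)                 # bone anchor
  expect_error(hu_to_mu(ct, 140, model), "not modelled")
})

test_that("Chang ACF is unity in vacuum", {
  mu <- mk_img(0, c(6, 6, 3), unit = "per_mm")
  body <- voi_mask(array(TRUE, c(6, 6, 3)), c(1, 1, 1))
  acf <- chang_acf(mu, body, n_angles = 16)
  expect_equal(acf$values, array(1, c(6, 6, 3)), tolerance = 1e-12)
})

test_that("Chang ACF at the centre of a uniform disk matches exp(mu r)", {
  n <- 45L
  sp <- 1
  cx <- (n + 1) / 2
  x <- (seq_len(n) - cx) * sp
  r2 <- outer(x^2, x^2, "+")
  disk <- r2 <= 20^2
  mu_vals <- array(0, c(n, n, 3))
  for (k in 1:3) mu_vals[, , k] <- 0.015 * disk
  mu <- scalar_image(mu_vals, c(sp, sp, sp), unit = "per_mm")
  body <- voi_mask(array(rep(disk, 3), c(n, n, 3)), c(sp, sp, sp))
  acf <- chang_acf(mu, body, n_angles = 64)
  centre <- acf$values[cx, cx, 2]
  expect_lt(abs(centre - exp(0.3)) / exp(0.3), 0.005)
  ## ACF >= 1 inside the body, == 1 outside
  expect_true(all(acf$values[body$values] >= 1))
  expect_true(all(acf$values[!body$values] == 1))
})

test_that("Chang ACF is converged in the number of angles", {
  n <- 25L
  x <- seq_len(n) - (n + 1) / 2
  r2 <- outer(x^2, x^2, "+")
  blob <- 0.02 * exp(-r2 / (2 * 36))  # smooth mu bump
  mu_vals <- array(rep(blob, 3), c(n, n, 3))
  mu <- scalar_image(mu_vals, c(1, 1, 1), unit = "per_mm")
  body <- voi_mask(array(TRUE, c(n, n, 3)), c(1, 1, 1))
  a64 <- chang_acf(mu, body, n_angles = 64)
  a128 <- chang_acf(mu, body, n_angles = 128)
  expect_lt(max(abs(a128$values - a64$values) / a64$values), 0.002)
})

test_that("raising mu anywhere never lowers any ACF", {
  set.seed(17)
  n <- 13L
  base <- array(runif(n * n * 3, 0, 0.01), c(n, n, 3))
  bump <- base
  bump[5:8, 5:8, 2] <- bump[5:8, 5:8, 2] + 0.02
  body <- voi_mask(array(TRUE, c(n, n, 3)), c(1, 1, 1))
  a1 <- chang_acf(scalar_image(base, c(1, 1, 1), unit = "per_mm"), body, 16)
  a2 <- chang_acf(scalar_image(bump, c(1, 1, 1), unit = "per_mm"), body, 16)
  expect_true(all(a2$values >= a1$values - 1e-12))
})

test_that("ACF weighting is the stated convex combination", {
  a <- mk_img(1.40, unit = "acf")
  b <- mk_img(1.30, unit = "acf")
  comb <- combine_acf(a, b)
  expect_equal(comb$values[1, 1, 1], 0.635 * 1.40 + 0.365 * 1.30,
               tolerance = 1e-12)
  same <- combine_acf(a, a)
  expect_equal(same$values, a$values)
  ## combined map lies voxelwise between its inputs
  set.seed(5)
  av <- mk_img(1 + runif(8), unit = "acf")
  bv <- mk_img(1 + runif(8), unit = "acf")
  cv <- combine_acf(av, bv)
  lo <- pmin(av$values, bv$values)
  hi <- pmax(av$values, bv$values)
  expect_true(all(cv$values >= lo - 1e-12 & cv$values <= hi + 1e-12))
  expect_error(attenuation_model(weights = c(0.7, 0.365)), "sum to 1")
})

test_that("attenuation application is a voxelwise product", {
  img <- mk_img(10)
  acf <- mk_img(1.35, unit = "acf")
  expect_equal(apply_attenuation(img, acf)$values[1, 1, 1], 13.5)
  one <- mk_img(1, unit = "acf")
  expect_equal(apply_attenuation(img, one)$values, img$values)
  shifted <- scalar_image(array(1.2, c(2, 2, 2)), c(1, 1, 1),
                          origin = c(9, 9, 9), unit = "acf")
  expect_error(apply_attenuation(img, shifted), "same grid")
})

test_that("per-peak Chang correction undoes the matched forward attenuation", {
  ## forward model attenuates by 1/ACF voxelwise; with no blur/scatter the
  ## per-peak correction must restore the activity-proportional sum
  spec <- phantom_tube(2, spect_spacing = 1.0, ct_spacing = 0.8)
  ras <- rasterize_phantom(spec)
  cfg <- simulation_config(psf_fwhm_mm = 0, scatter_fraction = 0,
                           noise = "none")
  w <- simulate_windows(ras$activity, ras$ct, cfg)
  corr <- correct_windows(w, ras$ct, pipeline_params(psf = psf_model(0)))
  got <- sum(apply_attenuation(corr$peak1, corr$acf171)$values) +
    sum(apply_attenuation(corr$peak2, corr$acf245)$values)
  want <- 2110 * (0.9061 + 0.9412) * 2
  expect_lt(abs(got - want) / want, 0.01)
})

test_that("MGM with a delta PSF is the identity inside the target", {
  set.seed(8)
  vals <- array(runif(6^3), c(6, 6, 6))
  img <- scalar_image(vals, c(1, 1, 1), unit = "cps")
  tgt <- array(FALSE, c(6, 6, 6))
  tgt[2:5, 2:5, 2:5] <- TRUE
  target <- voi_mask(tgt, c(1, 1, 1))
  out <- mgm_correct(img, target, NULL, psf_model(0))
  expect_equal(out$values[tgt], vals[tgt], tolerance = 1e-12)
  expect_true(all(out$values[!tgt] == 0))
})

test_that("MGM restores the mean of a blurred uniform sphere within 2%", {
  n <- 24L
  x <- seq_len(n) - (n + 1) / 2
  R2 <- array(0, c(n, n, n))
  for (k in seq_len(n)) R2[, , k] <- outer(x^2, x^2, "+") + x[k]^2
  sphere <- R2 <= 25  # radius 5 mm at 1 mm spacing
  img <- scalar_image(array(as.numeric(sphere), c(n, n, n)), c(1, 1, 1),
                      unit = "cps")
  blurred <- blur_gaussian(img, fwhm_mm = 2)
  target <- voi_mask(sphere, c(1, 1, 1))
  uncorrected <- mean(blurred$values[sphere])
  expect_lt(uncorrected, 1)
  fixed <- mgm_correct(blurred, target, NULL, psf_model(2))
  expect_lt(abs(mean(fixed$values[sphere]) - 1), 0.02)
})

test_that("MGM removes hot-background spill-in around a cool target", {
  n <- 30L
  x <- seq_len(n) - (n + 1) / 2
  R2 <- array(0, c(n, n, n))
  for (k in seq_len(n)) R2[, , k] <- outer(x^2, x^2, "+") + x[k]^2
  tgt <- R2 <= 16            # radius 4 target, value 0.2
  bg <- R2 > 16 & R2 <= 144  # shell out to radius 12, value 0.5
  truth <- array(0, c(n, n, n))
  truth[tgt] <- 0.2
  truth[bg] <- 0.5
  img <- blur_gaussian(scalar_image(truth, c(1, 1, 1), unit = "cps"),
                       fwhm_mm = 3)
  uncorr_err <- abs(mean(img$values[tgt]) - 0.2) / 0.2
  expect_gt(uncorr_err, 0.2)
  out <- mgm_correct(img, voi_mask(tgt, c(1, 1, 1)),
                     voi_mask(bg, c(1, 1, 1)), psf_model(3))
  corr_err <- abs(mean(out$values[tgt]) - 0.2) / 0.2
  expect_lt(corr_err, 0.05)
})

test_that("MGM refuses a target far smaller than the PSF", {
  n <- 13L
  tgt <- array(FALSE, c(n, n, n))
  tgt[7, 7, 7] <- TRUE
  img <- scalar_image(array(1, c(n, n, n)), c(1, 1, 1), unit = "cps")
  expect_error(
    mgm_correct(img, voi_mask(tgt, c(1, 1, 1)), NULL, psf_model(10),
                recovery_floor = 0.5),
    "too small")
})

test_that("Gaussian blur matches a direct convolution oracle", {
  set.seed(2)
  x <- runif(15)
  k <- gdspect:::gaussian_kernel_1d(1.3)
  arr <- array(0, c(15, 1, 1))
  arr[, 1, 1] <- x
  got <- gdspect:::convolve_axis(arr, k, 1L)[, 1, 1]
  expect_equal(got, conv1_brute(x, k), tolerance = 1e-12)
  expect_equal(sum(k), 1, tolerance = 1e-12)
})
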