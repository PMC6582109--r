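test_that("image construction enforces geometry and unit invariants", {
  expect_error(scalar_image(array(1, c(2, 2, 2)), c(0, 1, 1)),
               "strictly positive")
  a <- array(1, c(2, 2, 2))
  a[2, 1, 2] <- NaN
  expect_error(scalar_image(a, c(1, 1, 1)), "\\(2, 1, 2\\)")
  b <- array(-1, c(2, 2, 2))
  expect_error(scalar_image(b, c(1, 1, 1), unit = "cps"), "negative")
  expect_error(scalar_image(array(0.5, c(2, 2, 2)), c(1, 1, 1),
                            unit = "acf"), "< 1")
  expect_silent(scalar_image(b, c(1, 1, 1), unit = "HU"))
})

test_that("write/read roundtrip is lossless for NIfTI and MetaImage", {
  set.seed(11)
  img <- scalar_image(array(runif(64), c(4, 4, 4)), c(0.6, 0.6, 0.6),
                      origin = c(-1, 2, 3.5), unit = "cps")
  for (ext in c(".nii.gz", ".mha", ".mhd")) {
    f <- file.path(withr::local_tempdir(), paste0("img", ext))
    write_image(img, f, window = "peak171")
    back <- read_image(f, expected_unit = "cps")
    tol <- if (ext == ".nii.gz") 1e-12 else 1e-7  # MetaImage is float32
    expect_equal(back$values, img$values, tolerance = tol)
    expect_equal(back$spacing, img$spacing, tolerance = 1e-6)
    expect_equal(back$origin, img$origin, tolerance = 1e-6)
    expect_true(file.exists(paste0(f, ".json")))
  }
})

test_that("reading a file with a non-finite voxel is a validation error", {
  f <- file.path(withr::local_tempdir(), "bad.nii.gz")
  a <- array(1, c(3, 3, 3))
  a[2, 2, 2] <- NaN
  RNifti::writeNifti(RNifti::asNifti(a), f)
  expect_error(read_image(f), "non-finite voxel")
})

test_that("CT and SPECT grids with device voxel sizes are distinct grids", {
  ct <- scalar_image(array(0, c(6, 6, 6)), rep(0.4, 3), unit = "HU")
  spect <- scalar_image(array(0, c(4, 4, 4)), rep(0.6, 3), unit = "cps")
  expect_false(same_grid(ct, spect))
  expect_true(same_grid(ct, ct))
})

test_that("resampling onto the same grid is the identity", {
  set.seed(4)
  img <- scalar_image(array(runif(5 * 4 * 3), c(5, 4, 3)), c(1, 1.5, 2),
                      origin = c(0.3, -1, 2))
  out <- resample_to_grid(img, img, "linear")
  expect_equal(out$values, img$values, tolerance = 1e-12)
})

test_that("a constant image stays constant on a refined grid", {
  img <- scalar_image(array(7, c(6, 6, 6)), c(1, 1, 1))
  ref <- scalar_image(array(0, c(11, 11, 11)), c(0.5, 0.5, 0.5))
  out <- resample_to_grid(img, ref, "linear")
  inside <- out$values[2:10, 2:10, 2:10]
  expect_true(all(abs(inside - 7) < 1e-12))
})

test_that("linear resampling reproduces a linear ramp exactly", {
  nx <- 9L
  vals <- array(rep(seq(0, 8), times = 9), c(nx, 3, 3))
  img <- scalar_image(vals, c(2, 2, 2))  # ramp slope 0.5 per mm along x
  ref <- scalar_image(array(0, c(2 * nx - 1, 3, 3)), c(1, 2, 2),
                      origin = img$origin)
  out <- resample_to_grid(img, ref, "linear")
  x <- ref$origin[1] + (seq_len(2 * nx - 1) - 1) * 1
  expected <- (x - img$origin[1]) / 2
  expect_lt(max(abs(out$values[, 2, 2] - expected)), 1e-9)
})

test_that("nearest-neighbour resampling of a binary mask stays binary", {
  set.seed(9)
  m <- voi_mask(array(runif(6^3) > 0.5, c(6, 6, 6)), c(1, 1, 1))
  ref <- scalar_image(array(0, c(9, 9, 9)), c(0.7, 0.7, 0.7),
                      origin = c(-0.2, -0.2, -0.2))
  out <- resample_mask(m, ref)
  expect_true(is.logical(out$values))
  expect_equal(out$provenance, m$provenance)
})

test_that("integer-factor grid refinement conserves the physical total", {
  set.seed(21)
  vals <- array(0, c(10, 10, 10))
  vals[4:7, 4:7, 4:7] <- runif(64) + 1  # compact support away from edges
  img <- scalar_image(vals, c(1, 1, 1))
  ref <- scalar_image(array(0, c(30, 30, 30)), rep(1 / 3, 3),
                      origin = img$origin - 1 / 3)
  out <- resample_to_grid(img, ref, "linear")
  tot_src <- sum(img$values) * prod(img$spacing)
  tot_dst <- sum(out$values) * prod(ref$spacing)
  expect_lt(abs(tot_dst - tot_src) / tot_src, 0.01)
})

test_that("disjoint physical extents raise a geometry error", {
  a <- scalar_image(array(1, c(4, 4, 4)), c(1, 1, 1), origin = c(0, 0, 0))
  b <- scalar_image(array(1, c(4, 4, 4)), c(1, 1, 1),
                    origin = c(100, 0, 0))
  expect_error(resample_to_grid(a, b), "disjoint")
})

test_that("mask volume is exactly voxel count times voxel volume", {
  m <- voi_mask(array(c(TRUE, FALSE), c(5, 4, 3)), c(0.6, 0.6, 0.6))
  expect_equal(mask_volume_mL(m), sum(m$values) * 0.6^3 / 1000)
  expect_error(voi_mask(array(0.5, c(2, 2, 2)), c(1, 1, 1)), "binary")
})
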