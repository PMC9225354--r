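test_that("volume containers validate their invariants", {
  expect_error(ct_volume(matrix(0, 2, 2), 0.1), "3-D")
  expect_error(ct_volume(array(0, c(2, 2, 2)), -1), "positive")
  v <- ct_volume(array(rnorm(8), c(2, 2, 2)), 0.082, modality = "HRpQCT")
  expect_s3_class(v, "ct_volume")
  expect_identical(dim(v), c(2L, 2L, 2L))
})

test_that("volumes round-trip through NIfTI and raw+sidecar", {
  set.seed(42)
  v <- ct_volume(array(rnorm(60, 0, 300), c(5, 4, 3)), 0.0084,
                 modality = "microCT")
  for (ext in c("vol.nii.gz", "vol.raw")) {
    p <- file.path(withr::local_tempdir(), ext)
    write_volume(v, p)
    back <- read_volume(p)
    expect_equal(back$values, v$values, tolerance = 0)
    expect_equal(back$voxel_size_mm, v$voxel_size_mm)
    expect_identical(back$modality, "microCT")
  }
})

test_that("TIFF stacks read with sidecar geometry (animal preset layout)", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "stack.tif")
  # 60-slice stack, values as 16-bit integers
  slices <- lapply(1:60, function(i) matrix(i / 65535, 8, 8))
  tiff::writeTIFF(slices, p, bits.per.sample = 16L)
  yaml::write_yaml(list(voxel_size_mm = 0.0084, modality_tag = "microCT"),
                   paste0(p, ".yaml"))
  v <- read_volume(p)
  expect_identical(dim(v), c(8L, 8L, 60L))
  expect_equal(v$voxel_size_mm, 0.0084)
  expect_equal(as.vector(v$values[1, 1, ]), 1:60)
})

test_that("degenerate volume inputs fail loudly", {
  dir <- withr::local_tempdir()
  p2 <- file.path(dir, "one.tif")
  tiff::writeTIFF(matrix(0.5, 6, 6), p2)
  yaml::write_yaml(list(voxel_size_mm = 0.01), paste0(p2, ".yaml"))
  expect_error(read_volume(p2), "3-D")
  p3 <- file.path(dir, "nosidecar.raw")
  writeBin(rnorm(8), p3)
  expect_error(read_volume(p3), "sidecar")
  expect_error(read_volume(file.path(dir, "absent.nii")), "no such file")
})

test_that("HU calibration is linear, anchored and order preserving", {
  expect_error(hu_calibration(slope = 0), "nonzero")
  raw <- array(c(0L, 1000L, 250L, 500L, 750L, 100L, 900L, 42L), c(2, 2, 2))
  v <- apply_calibration(raw, hu_calibration(1, -1000), 0.082)
  expect_equal(v$values[1, 1, 1], -1000)  # air anchor
  expect_equal(v$values[2, 1, 1], 0)      # water anchor
  id <- apply_calibration(raw, hu_calibration(1, 0), 0.082)
  expect_equal(id$values, raw + 0)
  expect_true(all(order(raw) == order(v$values)))
})

test_that("Gaussian filter preserves constants and matches the convolution oracle", {
  const <- ct_volume(array(100, c(7, 7, 7)), 0.164)
  expect_equal(gaussian_filter_volume(const)$values, const$values)

  set.seed(7)
  a <- array(rnorm(343, 0, 200), c(7, 7, 7))
  v <- ct_volume(a, 0.164)
  got <- gaussian_filter_volume(v, filter_spec(2.5, 5))$values
  want <- oracle_gaussian(a, 2.5, 5)
  expect_lt(max(abs(got - want)) / max(abs(want)), 1e-9)

  # smaller kernel, non-cubic shape
  b <- array(rnorm(144, 0, 50), c(6, 4, 6))
  got2 <- gaussian_filter_volume(ct_volume(b, 0.1), filter_spec(1.2, 2))$values
  expect_lt(max(abs(got2 - oracle_gaussian(b, 1.2, 2))), 1e-9 * max(abs(got2)))
})

test_that("centered unit impulse reproduces the separable kernel product", {
  a <- array(0, c(11, 11, 11)); a[6, 6, 6] <- 1
  spec <- filter_spec(2.5, 5)
  got <- gaussian_filter_volume(ct_volume(a, 1), spec)$values
  k <- -5:5
  w <- exp(-(k^2) / (2 * 2.5^2)); w <- w / sum(w)
  expect_equal(got[6, 6, 6], w[6]^3, tolerance = 1e-12)
  expect_equal(got[8, 6, 5], w[8] * w[6] * w[5], tolerance = 1e-12)
})

test_that("global mean is preserved by filtering within tolerance", {
  set.seed(9)
  a <- array(rnorm(9^3, 100, 30), c(9, 9, 9))
  f <- gaussian_filter_volume(ct_volume(a, 1))$values
  expect_equal(mean(f), mean(oracle_gaussian(a, 2.5, 5)), tolerance = 1e-12)
})

test_that("downscaling is exact block averaging with geometry update", {
  v <- ct_volume(array(5, c(4, 4, 4)), 0.082)
  d <- downscale_volume(v, 2L)
  expect_identical(dim(d), c(2L, 2L, 2L))
  expect_true(all(d$values == 5))
  expect_equal(d$voxel_size_mm, 0.164)

  blk <- array(c(0, 100, 0, 100, 100, 0, 100, 0), c(2, 2, 2))
  expect_equal(downscale_volume(ct_volume(blk, 1), 2L)$values[1, 1, 1], 50)

  expect_error(downscale_volume(v, 1L), ">= 2")

  set.seed(3)
  a <- array(rnorm(6^3), c(6, 6, 6))
  expect_equal(mean(downscale_volume(ct_volume(a, 1), 2L)$values), mean(a))
  # trailing voxels dropped
  b <- array(rnorm(7 * 6 * 6), c(7, 6, 6))
  expect_identical(dim(downscale_volume(ct_volume(b, 1), 2L)$values), c(3L, 3L, 3L))
})
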