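test_that("ROI peeling matches the iterated min-filter oracle", {
  m <- array(FALSE, c(12, 12, 12)); m[2:11, 2:11, 2:11] <- TRUE  # 10^3 cube
  expect_identical(peel_roi(m, 0L), m)
  p3 <- peel_roi(m, 3L)
  expect_equal(sum(p3), 64)                      # (10 - 2*3)^3
  expect_identical(p3, oracle_erode(m, 3))
  # random blob against the oracle
  set.seed(2)
  b <- array(runif(8^3) > 0.4, c(8, 8, 8))
  expect_identical(peel_roi(b, 2L), oracle_erode(b, 2))
})

test_that("peeling is anti-extensive and composes additively", {
  set.seed(3)
  m <- array(runif(10^3) > 0.3, c(10, 10, 10))
  p1 <- peel_roi(m, 1L)
  expect_true(all(which(p1) %in% which(m)))
  expect_identical(peel_roi(p1, 1L), peel_roi(m, 2L))
  # a 5-voxel slab peeled by 3 vanishes
  slab <- array(FALSE, c(20, 20, 9)); slab[2:19, 2:19, 3:7] <- TRUE
  expect_false(any(peel_roi(slab, 3L)))
})

test_that("IMAT segmentation is the fat band inside the peeled ROI", {
  a <- array(300, c(8, 8, 8))
  a[4:5, 4:5, 4:5] <- -300
  v <- ct_volume(a, 0.164)
  roi <- array(TRUE, c(8, 8, 8))
  cfg <- imat_config("HRpQCT")
  m <- segment_imat(v, roi, cfg)
  expect_identical(m, array(a >= -600 & a <= -20, dim(a)))
  # empty ROI warns and returns empty
  expect_warning(m0 <- segment_imat(v, array(FALSE, dim(a)), cfg), "empty")
  expect_false(any(m0))
  # micro-CT band excludes everything above 100 HU
  hot <- ct_volume(array(200, c(4, 4, 4)), 0.0084)
  expect_false(any(segment_imat(hot, array(TRUE, c(4, 4, 4)),
                                imat_config("microCT"))))
  # widening the band never shrinks the mask
  wide <- segment_imat(v, roi, imat_config("custom", imat_band = c(-700, 50)))
  expect_true(all(which(m) %in% which(wide)))
})

test_that("preset bands carry the two workflows", {
  expect_equal(imat_config("microCT")$imat_band, c(-600, 100))
  expect_equal(imat_config("HRpQCT")$imat_band, c(-600, -20))
  expect_equal(imat_config("HRpQCT")$peel_vox, 3L)
  expect_error(imat_config("custom"), "imat_band")
})

test_that("metrics implement the outcome definitions", {
  d <- c(10, 10, 10)
  a <- array(-1000, d)
  roi <- array(FALSE, d)
  roi[4:6, 4, 4] <- TRUE
  a[4:6, 4, 4] <- c(100, 200, 300)
  labels <- array(0L, d); labels[roi] <- 3L
  seg <- tissue_segmentation(labels, 1, muscle_roi = roi)
  cfg <- imat_config("HRpQCT", peel_vox = 0L)
  m <- compute_metrics(ct_volume(a, 1), seg, array(FALSE, d), cfg)
  expect_equal(m$MD, 200)
  expect_equal(m$IMAT_pct, 0)
  expect_equal(m$MCSA, m$MV / (d[3] * 1))

  # 1000-voxel ROI with 100 IMAT voxels
  roi2 <- array(FALSE, d); roi2[1:10, 1:10, 1:10] <- TRUE
  a2 <- array(300, d); a2[1:4, 1:5, 1:5] <- -300   # 100 voxels in band
  labels2 <- array(3L, d)
  seg2 <- tissue_segmentation(labels2, 1, muscle_roi = roi2)
  im <- segment_imat(ct_volume(a2, 1), roi2, cfg)
  m2 <- compute_metrics(ct_volume(a2, 1), seg2, im, cfg)
  expect_equal(m2$IMAT_pct, 10)
  expect_equal(m2$IMAT_over_MV, 100 / 900)
  expect_equal(m2$MD_lean, 300)

  # undefined rather than divide-by-zero on an empty ROI
  seg0 <- tissue_segmentation(array(0L, d), 1, muscle_roi = array(FALSE, d))
  suppressWarnings(
    m0 <- compute_metrics(ct_volume(a2, 1), seg0, array(FALSE, d), cfg))
  expect_true(is.na(m0$IMAT_pct) && is.na(m0$MCSA))
})

test_that("volume metrics scale with voxel volume, ratios do not", {
  set.seed(4)
  ph <- generate_ct_phantom(small_phantom_spec(rng_seed = 4))
  f <- gaussian_filter_volume(ph$volume)
  seg <- segment_soft_tissue(f)
  cfg <- imat_config("HRpQCT")
  roi_p <- peel_roi(seg$muscle_roi, cfg$peel_vox)
  im <- segment_imat(f, roi_p, cfg)
  m1 <- compute_metrics(f, seg, im, cfg, muscle_roi_peeled = roi_p)

  f2 <- f; f2$voxel_size_mm <- 2 * f$voxel_size_mm
  seg2 <- seg; seg2$voxel_size_mm <- f2$voxel_size_mm
  m2 <- compute_metrics(f2, seg2, im, cfg, muscle_roi_peeled = roi_p)
  expect_equal(m2$MV, 8 * m1$MV)
  expect_equal(m2$TV, 8 * m1$TV)
  expect_equal(m2$IMAT_V, 8 * m1$IMAT_V)
  expect_equal(m2$IMAT_pct, m1$IMAT_pct)
  expect_equal(m2$MD, m1$MD)
})

test_that("stack geometry gives MCSA as MV over stack height", {
  # 110 slices at 0.082 mm: height 9.02 mm; MV of 902 mm^3 -> MCSA 100 mm^2
  vx <- 0.082
  n_roi <- round(902 / vx^3)
  d <- c(160, 160, 110)
  roi <- array(FALSE, d)
  roi[seq_len(n_roi)] <- TRUE
  labels <- array(0L, d); labels[roi] <- 3L
  seg <- tissue_segmentation(labels, vx, muscle_roi = roi)
  cfg <- imat_config("HRpQCT", peel_vox = 0L)
  m <- compute_metrics(ct_volume(array(300, d), vx), seg, array(FALSE, d), cfg)
  expect_equal(m$stack_height_mm, 9.02)
  expect_equal(m$MV, n_roi * vx^3)
  expect_equal(m$MCSA, m$MV / 9.02)
  expect_equal(m$MCSA, 100, tolerance = 1e-3)
})
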