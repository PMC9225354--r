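# Helper: a small calibrated volume from an array.
vol_of <- function(a, vox = 0.164) ct_volume(a, vox)

test_that("threshold masks use closed intervals", {
  a <- array(c(-700, -600, 0, 100, 101, rep(-1000, 3)), c(2, 2, 2))
  v <- vol_of(a)
  m <- threshold_mask(v, -600, 100)
  expect_equal(sum(m), 3)                       # -600, 0, 100 included
  expect_true(all(threshold_mask(v, -1e9, 1e9)))
  expect_false(any(threshold_mask(v, 5, 5)))
  expect_error(threshold_mask(v, 10, -10), "inverted")
  # brute-force per-voxel check on random data
  set.seed(1)
  b <- array(runif(4^3, -1000, 1000), c(4, 4, 4))
  expect_identical(threshold_mask(vol_of(b), -250, 250),
                   array(b >= -250 & b <= 250, dim(b)))
})

test_that("bone exclusion recovers dense structures and drops specks", {
  a <- array(0, c(20, 20, 8))
  a[5:8, 5:8, ] <- 1500          # bone 1
  a[14:17, 12:15, ] <- 1500      # bone 2 (tibia + fibula analogue)
  a[2, 18, 3] <- 1500            # isolated speck
  cfg <- segmentation_config()
  bone <- exclude_bone(vol_of(a), cfg)
  truth <- a >= 600
  truth[2, 18, 3] <- FALSE
  # within one voxel of the true boundary after closing
  expect_true(all(bone[truth]))
  expect_true(all(which(bone) %in% which(mask_dilate(truth, 1L))))
  expect_equal(max(label_components(bone)), 2L)
  expect_false(any(exclude_bone(vol_of(array(0, c(5, 5, 5))), cfg)))
})

test_that("skin exclusion peels inward from border-connected air only", {
  a <- array(-1000, c(24, 24, 8))
  a[3:22, 3:22, ] <- 300                    # tissue block
  a[10:12, 10:12, 4:5] <- -1000             # internal air pocket
  cfg0 <- segmentation_config(skin_depth_vox = 0L)
  expect_false(any(exclude_skin(vol_of(a), cfg0)))
  cfg2 <- segmentation_config(skin_depth_vox = 2L)
  skin <- exclude_skin(vol_of(a), cfg2)
  # outer shell of depth 2 in x/y; z faces belong to the stack
  expect_true(all(skin[3:4, 12, 4]))
  expect_true(all(skin[21:22, 12, 4]))
  expect_false(any(skin[6:19, 6:19, ]))
  # the internal pocket is not exterior: its surroundings stay unpeeled
  expect_false(any(skin[9:13, 9:13, 3:6]))
  expect_error(exclude_skin(vol_of(array(300, c(6, 6, 6))), cfg2),
               "no exterior")
})

test_that("seed planting erodes, size-filters, and respects ground truth", {
  set.seed(5)
  ph <- generate_ct_phantom(small_phantom_spec(fat_fraction = 0, rng_seed = 5))
  f <- gaussian_filter_volume(ph$volume)
  cfg <- segmentation_config()
  seeds <- plant_seeds(f, cfg$muscle_band, cfg)
  truth_muscle <- ph$truth$labels == 3L
  expect_gt(sum(seeds), 0)
  expect_true(all(which(seeds) %in% which(truth_muscle)))

  # speckles below the minimum size are removed
  a <- array(-1000, c(12, 12, 12))
  a[3:8, 3:8, 3:8] <- 300                    # survives erosion + size filter
  a[11, 11, 11] <- 300                       # single-voxel speck
  s <- plant_seeds(vol_of(a), c(100, 600), cfg)
  expect_equal(sum(s), 4^3)
  expect_false(s[11, 11, 11])
  expect_false(any(plant_seeds(vol_of(array(0, c(6, 6, 6))), c(100, 600), cfg)))
})

test_that("region growing equals BFS flood fill at convergence", {
  set.seed(11)
  for (trial in 1:3) {
    d <- c(14, 12, 10)
    a <- array(-1000, d)
    # random muscle blobs
    n_blob <- 6
    for (i in seq_len(n_blob)) {
      c0 <- c(sample(d[1], 1), sample(d[2], 1), sample(d[3], 1))
      r <- sample(2:4, 1)
      xr <- max(1, c0[1] - r):min(d[1], c0[1] + r)
      yr <- max(1, c0[2] - r):min(d[2], c0[2] + r)
      zr <- max(1, c0[3] - r):min(d[3], c0[3] + r)
      a[xr, yr, zr] <- 300
    }
    seed_idx <- sample(which(a == 300), 1)
    seeds <- array(FALSE, d); seeds[seed_idx] <- TRUE
    cfg <- segmentation_config(iterations = 200L, relaxed_margin_hu = 0)
    seg <- region_grow(vol_of(a), seeds, array(FALSE, d), cfg)
    got <- segmentation_mask(seg, "muscle")
    want <- oracle_flood_fill(a, seed_idx, 100, 600)
    expect_identical(got, want)
  }
})

test_that("one growth round adds exactly the band-eligible neighbours", {
  a <- array(-1000, c(7, 1, 1))
  a[, 1, 1] <- c(300, 300, -1000, 300, 300, 300, 300)
  seeds <- array(FALSE, dim(a)); seeds[4, 1, 1] <- TRUE
  cfg <- segmentation_config(iterations = 1L, relaxed_margin_hu = 0)
  seg <- region_grow(vol_of(a), seeds, array(FALSE, dim(a)), cfg)
  expect_identical(which(segmentation_mask(seg, "muscle")), c(4L, 5L))
})

test_that("growth is monotone in iterations and needs seeds", {
  set.seed(21)
  ph <- generate_ct_phantom(small_phantom_spec(rng_seed = 21))
  f <- gaussian_filter_volume(ph$volume)
  seeds_m <- plant_seeds(f, c(100, 600), segmentation_config())
  seeds_f <- plant_seeds(f, c(-600, -200), segmentation_config()) & !seeds_m
  prev <- NULL
  for (it in c(2L, 5L, 9L)) {
    cfg <- segmentation_config(iterations = it)
    m <- segmentation_mask(region_grow(f, seeds_m, seeds_f, cfg), "muscle")
    if (!is.null(prev)) expect_true(all(which(prev) %in% which(m)))
    prev <- m
  }
  none <- region_grow(f, array(FALSE, dim(f$values)),
                      array(FALSE, dim(f$values)), segmentation_config())
  expect_equal(sum(segmentation_mask(none, "muscle")), 0)
  expect_equal(sum(segmentation_mask(none, "subcut_fat")), 0)
  expect_error(region_grow(f, seeds_m, seeds_m, segmentation_config()),
               "overlapping")
})

test_that("contested voxels go to the nearer band midpoint, ties to muscle", {
  # strip: muscle seed | contested voxel | fat seed
  a <- array(NA_real_, c(3, 1, 1))
  a[, 1, 1] <- c(350, -25, -400)   # -25 equidistant from midpoints 350, -400
  seeds_m <- array(c(TRUE, FALSE, FALSE), c(3, 1, 1))
  seeds_f <- array(c(FALSE, FALSE, TRUE), c(3, 1, 1))
  cfg <- segmentation_config(iterations = 1L, relaxed_margin_hu = 1000)
  seg <- region_grow(vol_of(a), seeds_m, seeds_f, cfg)
  expect_equal(seg$labels[2, 1, 1], 3L)      # muscle wins the tie
  a[2, 1, 1] <- -300                         # clearly fat-like
  seg2 <- region_grow(vol_of(a), seeds_m, seeds_f, cfg)
  expect_equal(seg2$labels[2, 1, 1], 4L)
})

test_that("repeated runs of the vectorised growth are identical", {
  set.seed(31)
  ph <- generate_ct_phantom(small_phantom_spec(rng_seed = 31))
  f <- gaussian_filter_volume(ph$volume)
  s1 <- segment_soft_tissue(f)
  s2 <- segment_soft_tissue(f)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$muscle_roi, s2$muscle_roi)
})

test_that("full segmentation partitions the volume and handles all-air input", {
  set.seed(41)
  ph <- generate_ct_phantom(small_phantom_spec(rng_seed = 41))
  f <- gaussian_filter_volume(ph$volume)
  seg <- segment_soft_tissue(f)
  counts <- vapply(c("air", "skin", "bone", "muscle", "subcut_fat", "unassigned"),
                   function(t) sum(segmentation_mask(seg, t)), numeric(1))
  expect_equal(sum(counts), prod(dim(f$values)))   # conservation
  # exclusive labels: each voxel exactly one code
  expect_true(all(seg$labels %in% 0:5))
  # muscle ROI tracks the true compartment closely even on the small phantom
  truth_muscle <- ph$truth$labels == 3L
  expect_gt(dice_coefficient(seg$muscle_roi, truth_muscle), 0.9)

  air <- vol_of(array(-1000, c(12, 12, 6)))
  seg_air <- segment_soft_tissue(air)
  expect_true(all(seg_air$labels == 0L))
  expect_false(any(seg_air$muscle_roi))
})
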