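# Synthetic-data generators: a leg-cross-section CT phantom with ground-truth
# masks and known intramuscular fat fraction, synthetic ORO-stained images
# with an exact positive-pixel count, and a linear-Gaussian ageing-cohort
# simulator with closed-form population correlations.

#' CT phantom specification
#'
#' Concentric cylinders along the slice axis: cortical bone core, muscle
#' annulus with ellipsoidal IMAT inclusions, subcutaneous fat ring, thin skin
#' shell, exterior air. An optional deep-fascia shell (fat-free muscle-HU
#' voxels at the outer edge of the muscle compartment that inclusions never
#' cross) can be enabled; by default inclusions are clipped at the
#' compartment boundary itself, which keeps the expected IMAT density
#' uniform across the compartment and hence keeps the peeled-ROI estimator
#' unbiased with respect to the compartment-wide true fraction. Tissue HU means sit inside the protocol's own bands
#' (muscle 300 in 100..600, fat -400 in -600..-200, air -1000, skin 0, bone
#' 1500); Gaussian HU noise is added per voxel. The default grid is
#' 256 x 256 x 110 at 0.082 mm, the native resolution and slice count of the
#' human scanning protocol. Inclusions are prolate ellipsoids elongated
#' along the slice axis (fat streaks follow the muscle fibre direction),
#' with default transverse semi-axes 8..11 voxels (about 0.7-0.9 mm) and
#' axial semi-axes 16..22 voxels, large enough for the fat band to resolve
#' them after the sigma 2.5 protocol filter; centers are sampled uniformly
#' over the expanded neighbourhood of the compartment and clipped to it, so
#' the expected IMAT density is spatially uniform.
#'
#' @param shape_vox Length-3 integer grid size.
#' @param voxel_size_mm Isotropic voxel size.
#' @param leg_radius_frac Leg radius as a fraction of half the smaller
#'   transverse extent.
#' @param bone_radius_frac Bone radius as a fraction of the leg radius.
#' @param skin_thickness_vox Skin shell thickness in voxels.
#' @param subcut_fat_thickness_frac Subcutaneous ring thickness as a fraction
#'   of the leg radius.
#' @param fascia_thickness_vox Thickness (voxels) of an optional fat-free
#'   fascia shell at the outer edge of the muscle compartment; 0 disables it.
#' @param fat_fraction Target intramuscular fat volume fraction in [0, 1].
#' @param inclusion_radius_vox Length-2 integer (min, max) transverse
#'   semi-axis range in voxels.
#' @param inclusion_length_vox Length-2 integer (min, max) axial (slice-axis)
#'   semi-axis range in voxels.
#' @param hu_means Named list of tissue mean HU values.
#' @param hu_noise_sd Gaussian noise standard deviation in HU.
#' @param rng_seed Integer seed; the generator is deterministic given it.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape_vox = c(256L, 256L, 110L),
                         voxel_size_mm = 0.082,
                         leg_radius_frac = 0.85,
                         bone_radius_frac = 0.22,
                         skin_thickness_vox = 4L,
                         subcut_fat_thickness_frac = 0.25,
                         fascia_thickness_vox = 0L,
                         fat_fraction = 0.10,
                         inclusion_radius_vox = c(8L, 11L),
                         inclusion_length_vox = c(16L, 22L),
                         hu_means = list(air = -1000, skin = 0,
                                         subcut_fat = -400, muscle = 300,
                                         imat = -400, bone = 1500),
                         hu_noise_sd = 30,
                         rng_seed = 1L) {
  shape_vox <- as.integer(shape_vox)
  if (length(shape_vox) != 3L || any(shape_vox < 8L))
    stop("shape_vox must be 3 integers >= 8")
  if (fat_fraction < 0 || fat_fraction > 1) stop("fat_fraction must be in [0, 1]")
  if (leg_radius_frac <= 0 || leg_radius_frac > 1) stop("leg_radius_frac must be in (0, 1]")
  if (bone_radius_frac <= 0 || bone_radius_frac >= 1) stop("bone_radius_frac must be in (0, 1)")
  if (subcut_fat_thickness_frac < 0 || subcut_fat_thickness_frac >= 1)
    stop("subcut_fat_thickness_frac must be in [0, 1)")
  inclusion_radius_vox <- as.integer(inclusion_radius_vox)
  inclusion_length_vox <- as.integer(inclusion_length_vox)
  for (rr in list(inclusion_radius_vox, inclusion_length_vox)) {
    if (length(rr) != 2L || rr[1] < 1L || rr[1] > rr[2])
      stop("inclusion semi-axis ranges must be (min, max) integers >= 1")
  }
  needed <- c("air", "skin", "subcut_fat", "muscle", "imat", "bone")
  if (!all(needed %in% names(hu_means))) stop("hu_means must name all tissues")
  if (hu_noise_sd < 0) stop("hu_noise_sd must be >= 0")
  structure(list(shape_vox = shape_vox, voxel_size_mm = voxel_size_mm,
                 leg_radius_frac = leg_radius_frac,
                 bone_radius_frac = bone_radius_frac,
                 skin_thickness_vox = as.integer(skin_thickness_vox),
                 subcut_fat_thickness_frac = subcut_fat_thickness_frac,
                 fascia_thickness_vox = as.integer(fascia_thickness_vox),
                 fat_fraction = fat_fraction,
                 inclusion_radius_vox = inclusion_radius_vox,
                 inclusion_length_vox = inclusion_length_vox,
                 hu_means = hu_means, hu_noise_sd = hu_noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# Place ellipsoidal inclusions until the achieved fraction is within
# fraction_tol of the target. Inclusions are prolate along the slice axis
# (fat streaks run along the muscle fibre direction). Centers are sampled
# uniformly over the bounding box of the compartment expanded by the maximum
# semi-axes, and inclusions are clipped to the compartment: sampling centers
# only inside the compartment would leave a depleted layer (coverage ramps
# from rho/2 at the boundary to rho one radius in), whereas expanded-center
# sampling with clipping gives spatially uniform expected density, which is
# what makes a peeled-ROI estimate comparable to the compartment-wide true
# fraction. When the remaining volume budget is smaller than a full-size
# inclusion, smaller top-off inclusions are used so the target can be hit.
.place_inclusions <- function(muscle, spec, n_ref = sum(muscle),
                              fraction_tol = 0.002, max_attempts = 20000L) {
  target <- spec$fat_fraction * n_ref
  tol <- fraction_tol * n_ref
  imat <- array(FALSE, dim(muscle))
  if (target < 1) return(imat)
  mus_idx <- which(muscle)
  d <- dim(muscle)
  coords <- arrayInd(mus_idx, d)
  rmax_all <- max(spec$inclusion_radius_vox[2], spec$inclusion_length_vox[2])
  clo <- pmax(1L, apply(coords, 2L, min) - rmax_all)
  chi <- pmin(d, apply(coords, 2L, max) + rmax_all)
  rmin <- spec$inclusion_radius_vox[1]; rmax <- spec$inclusion_radius_vox[2]
  lmin <- spec$inclusion_length_vox[1]; lmax <- spec$inclusion_length_vox[2]
  full_vol <- 4 / 3 * pi * rmin^2 * lmin
  count <- 0L
  attempts <- 0L
  while (count < target - tol) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("unachievable fat_fraction: inclusion placement did not converge")
    if (target - count < full_vol) {
      # top off with small inclusions to land inside the tolerance window
      radii <- c(rep(max(2L, rmin %/% 2L), 2L), max(4L, lmin %/% 2L))
    } else {
      radii <- c(rep(sample(rmin:rmax, 1L), 2L), sample(lmin:lmax, 1L))
    }
    ci <- c(sample(clo[1]:chi[1], 1L), sample(clo[2]:chi[2], 1L),
            sample(clo[3]:chi[3], 1L))
    xr <- pmax(1L, ci[1] - radii[1]):pmin(d[1], ci[1] + radii[1])
    yr <- pmax(1L, ci[2] - radii[2]):pmin(d[2], ci[2] + radii[2])
    zr <- pmax(1L, ci[3] - radii[3]):pmin(d[3], ci[3] + radii[3])
    gx <- ((xr - ci[1]) / radii[1])^2
    gy <- ((yr - ci[2]) / radii[2])^2
    gz <- ((zr - ci[3]) / radii[3])^2
    inside <- outer(outer(gx, gy, "+"), gz, "+") <= 1
    sub <- muscle[xr, yr, zr, drop = FALSE] & inside & !imat[xr, yr, zr, drop = FALSE]
    added <- sum(sub)
    if (added == 0L) next
    if (count + added > target + tol) next  # would overshoot; resample
    blk <- imat[xr, yr, zr, drop = FALSE]
    blk[sub] <- TRUE
    imat[xr, yr, zr] <- blk
    count <- count + added
  }
  imat
}

#' Generate a leg CT phantom with ground truth
#'
#' Deterministic given \code{spec$rng_seed}. Returns the noisy HU volume and
#' a ground-truth object holding the tissue label volume (muscle code covers
#' the whole muscle compartment, inclusions included), the IMAT mask, the
#' achieved fat fraction (within 0.002 of the target) and true metrics
#' computed from the labels with the same peel depth the pipeline uses.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @param peel_vox Peel depth used for the true metrics (default 3).
#' @return A list with elements \code{volume} (\code{ct_volume}) and
#'   \code{truth} (list: labels, imat_mask, true_fat_fraction, true_metrics).
#' @export
generate_ct_phantom <- function(spec = phantom_spec(), peel_vox = 3L) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$rng_seed)
  d <- spec$shape_vox
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  r_leg <- spec$leg_radius_frac * (min(d[1], d[2]) / 2)
  r_bone <- spec$bone_radius_frac * r_leg
  r_skin_in <- r_leg - spec$skin_thickness_vox
  r_musc <- r_skin_in - spec$subcut_fat_thickness_frac * r_leg
  if (r_musc <= r_bone + 2) stop("phantom geometry leaves no muscle annulus")
  r2 <- outer((seq_len(d[1]) - cx)^2, (seq_len(d[2]) - cy)^2, "+")
  r <- sqrt(r2)
  slice_code <- matrix(SEG_CODES[["air"]], d[1], d[2])
  slice_code[r <= r_leg] <- SEG_CODES[["skin"]]
  slice_code[r <= r_skin_in] <- SEG_CODES[["subcut_fat"]]
  slice_code[r <= r_musc] <- SEG_CODES[["muscle"]]
  slice_code[r <= r_bone] <- SEG_CODES[["bone"]]
  labels <- array(rep(slice_code, d[3]), d)

  muscle <- labels == SEG_CODES[["muscle"]]
  # inclusions stay inside the fascial envelope
  core2d <- r <= r_musc - spec$fascia_thickness_vox & r > r_bone
  core <- muscle & array(rep(core2d, d[3]), d)
  imat <- .place_inclusions(core, spec, n_ref = sum(muscle))
  true_ff <- sum(imat) / sum(muscle)

  hu <- array(NA_real_, d)
  hu[labels == SEG_CODES[["air"]]] <- spec$hu_means$air
  hu[labels == SEG_CODES[["skin"]]] <- spec$hu_means$skin
  hu[labels == SEG_CODES[["subcut_fat"]]] <- spec$hu_means$subcut_fat
  hu[labels == SEG_CODES[["muscle"]]] <- spec$hu_means$muscle
  hu[labels == SEG_CODES[["bone"]]] <- spec$hu_means$bone
  hu[imat] <- spec$hu_means$imat
  if (spec$hu_noise_sd > 0)
    hu <- hu + stats::rnorm(length(hu), 0, spec$hu_noise_sd)
  vol <- ct_volume(hu, spec$voxel_size_mm, modality = "synthetic")

  # true metrics from the noiseless labels, same peel as the pipeline
  mean_hu <- array(NA_real_, d)
  mean_hu[labels == SEG_CODES[["air"]]] <- spec$hu_means$air
  mean_hu[labels == SEG_CODES[["skin"]]] <- spec$hu_means$skin
  mean_hu[labels == SEG_CODES[["subcut_fat"]]] <- spec$hu_means$subcut_fat
  mean_hu[labels == SEG_CODES[["muscle"]]] <- spec$hu_means$muscle
  mean_hu[labels == SEG_CODES[["bone"]]] <- spec$hu_means$bone
  mean_hu[imat] <- spec$hu_means$imat
  clean <- ct_volume(mean_hu, spec$voxel_size_mm, modality = "synthetic")
  seg_truth <- tissue_segmentation(labels, spec$voxel_size_mm,
                                   muscle_roi = muscle)
  roi_p <- peel_roi(muscle, peel_vox)
  cfg <- imat_config("HRpQCT", peel_vox = peel_vox)
  true_metrics <- compute_metrics(clean, seg_truth, imat & roi_p, cfg,
                                  muscle_roi_peeled = roi_p)

  list(volume = vol,
       truth = list(labels = labels, imat_mask = imat,
                    true_fat_fraction = true_ff,
                    true_metrics = true_metrics,
                    spec = spec))
}

#' Generate a synthetic ORO-stained histology image
#'
#' Blob-shaped positive regions are coloured with HSB values sampled strictly
#' inside the default ORO bands and the background strictly outside
#' (low-saturation pinkish white), then the positive set is adjusted pixel by
#' pixel so the positive count is exactly \code{round(positive_fraction * n)}.
#' Every pixel is verified against \code{\link{oro_positive_mask}} with the
#' default thresholds, so recovery of the truth is exact by construction.
#'
#' @param positive_fraction Target positive area fraction in [0, 1].
#' @param shape Length-2 integer image size; the default 240 x 240 makes
#'   common fractions exact.
#' @param rng_seed Integer seed.
#' @return A list with \code{image} (\code{histology_image}), \code{mask}
#'   (logical matrix) and \code{truth_pct} (exact positive percentage).
#' @export
generate_oro_image <- function(positive_fraction, shape = c(240L, 240L),
                               rng_seed = 1L) {
  if (positive_fraction < 0 || positive_fraction > 1)
    stop("positive_fraction must be in [0, 1]")
  set.seed(rng_seed)
  h <- shape[1]; w <- shape[2]
  n <- h * w
  target <- round(positive_fraction * n)

  mask <- matrix(FALSE, h, w)
  while (sum(mask) < target) {
    r <- sample(3:round(max(4, sqrt(target) / 2)), 1L)
    ci <- sample.int(h, 1L); cj <- sample.int(w, 1L)
    ii <- pmax(1L, ci - r):pmin(h, ci + r)
    jj <- pmax(1L, cj - r):pmin(w, cj + r)
    disc <- outer((ii - ci)^2, (jj - cj)^2, "+") <= r^2
    mask[ii, jj] <- mask[ii, jj] | disc
  }
  pos_idx <- which(mask)
  if (length(pos_idx) > target)
    mask[sample(pos_idx, length(pos_idx) - target)] <- FALSE

  # colours: positives inside the ORO bands with a safety margin against
  # 8-bit quantisation; background low-saturation (margin below 167)
  .hsb_to_rgb <- function(h255, s255, v255) {
    col <- grDevices::hsv(h255 / 255, s255 / 255, v255 / 255)
    t(grDevices::col2rgb(col))
  }
  npos <- sum(mask)
  img <- array(0, c(h, w, 3L))
  nbg <- n - npos
  bg <- .hsb_to_rgb(stats::runif(nbg, 200, 250), stats::runif(nbg, 10, 110),
                    stats::runif(nbg, 180, 250))
  for (ch in 1:3) { pl <- img[, , ch]; pl[!mask] <- bg[, ch]; img[, , ch] <- pl }
  if (npos > 0) {
    fg <- .hsb_to_rgb(stats::runif(npos, 232, 251), stats::runif(npos, 175, 250),
                      stats::runif(npos, 120, 245))
    for (ch in 1:3) { pl <- img[, , ch]; pl[mask] <- fg[, ch]; img[, , ch] <- pl }
  }
  him <- histology_image(img)
  # verify and repair any pixel that quantisation pushed across a band edge
  got <- oro_positive_mask(him, hsb_threshold())
  bad <- which(got != mask)
  guard <- 0L
  while (length(bad) > 0L && guard < 20L) {
    guard <- guard + 1L
    nb <- length(bad)
    want_pos <- mask[bad]
    repl_pos <- .hsb_to_rgb(stats::runif(nb, 235, 248), stats::runif(nb, 180, 245),
                            stats::runif(nb, 130, 240))
    repl_neg <- .hsb_to_rgb(stats::runif(nb, 205, 245), stats::runif(nb, 15, 100),
                            stats::runif(nb, 185, 245))
    px <- him$pixels
    for (ch in 1:3) {
      pl <- px[, , ch]
      pl[bad] <- ifelse(want_pos, repl_pos[, ch], repl_neg[, ch])
      px[, , ch] <- pl
    }
    him <- histology_image(px)
    got <- oro_positive_mask(him, hsb_threshold())
    bad <- which(got != mask)
  }
  if (length(bad) > 0L) stop("ORO fixture generation failed to stabilise")
  list(image = him, mask = mask, truth_pct = 100 * target / n)
}

#' Ageing-cohort specification
#'
#' Linear-Gaussian generative model: ages are uniform over \code{age_range};
#' muscle density declines and IMAT% rises linearly with age; chair rise time
#' rises with IMAT% and quadriceps strength rises with MD; muscle volume
#' declines with age. Each outcome adds independent Gaussian noise, so every
#' population correlation has a closed form (see
#' \code{\link{cohort_expected_correlations}}). Defaults are tuned so the key
#' population correlations sit near the magnitudes reported for a human
#' ageing cohort (age-MD about -0.76, age-IMAT% about +0.56, IMAT%-rise time
#' about +0.67, MD-quadriceps about +0.59, age-MV about -0.48).
#'
#' @param n_subjects Integer >= 3.
#' @param age_range Length-2 years, default 18..81.
#' @param md_intercept,md_age_slope MD model: HU at age 0 and HU/year (< 0).
#' @param imat_intercept,imat_age_slope IMAT% model: % at age 0 and %/year (> 0).
#' @param mv_intercept,mv_age_slope MV model: mm^3 and mm^3/year.
#' @param rise_intercept,rise_imat_slope Chair rise time: s and s per IMAT%.
#' @param strength_intercept,strength_md_slope Quadriceps strength: kg and kg/HU.
#' @param noise_sds Named list of Gaussian noise SDs (md, imat, mv, rise, strength).
#' @param rng_seed Integer seed.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_subjects = 30L,
                        age_range = c(18, 81),
                        md_intercept = 400, md_age_slope = -1.5,
                        imat_intercept = 2, imat_age_slope = 0.15,
                        mv_intercept = 40000, mv_age_slope = -100,
                        rise_intercept = 4, rise_imat_slope = 0.30,
                        strength_intercept = 10, strength_md_slope = 0.05,
                        noise_sds = list(md = 23.1, imat = 4.05, mv = 3334,
                                         rise = 1.62, strength = 2.46),
                        rng_seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 3L) stop("n_subjects must be >= 3")
  if (age_range[1] >= age_range[2]) stop("age_range inverted")
  slopes <- c(md_age_slope, imat_age_slope, mv_age_slope,
              rise_imat_slope, strength_md_slope)
  if (any(!is.finite(slopes))) stop("slopes must be finite")
  structure(list(n_subjects = n_subjects, age_range = as.numeric(age_range),
                 md_intercept = md_intercept, md_age_slope = md_age_slope,
                 imat_intercept = imat_intercept, imat_age_slope = imat_age_slope,
                 mv_intercept = mv_intercept, mv_age_slope = mv_age_slope,
                 rise_intercept = rise_intercept, rise_imat_slope = rise_imat_slope,
                 strength_intercept = strength_intercept,
                 strength_md_slope = strength_md_slope,
                 noise_sds = noise_sds, rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

#' Simulate an ageing cohort
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @return A \code{data.frame} with columns age, MD, IMAT_pct, MV, rise_time,
#'   quadriceps_strength.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$rng_seed)
  n <- spec$n_subjects
  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  md <- spec$md_intercept + spec$md_age_slope * age +
    stats::rnorm(n, 0, spec$noise_sds$md)
  imat <- spec$imat_intercept + spec$imat_age_slope * age +
    stats::rnorm(n, 0, spec$noise_sds$imat)
  imat <- pmax(imat, 0)
  mv <- spec$mv_intercept + spec$mv_age_slope * age +
    stats::rnorm(n, 0, spec$noise_sds$mv)
  rise <- spec$rise_intercept + spec$rise_imat_slope * imat +
    stats::rnorm(n, 0, spec$noise_sds$rise)
  strength <- spec$strength_intercept + spec$strength_md_slope * md +
    stats::rnorm(n, 0, spec$noise_sds$strength)
  data.frame(age = age, MD = md, IMAT_pct = imat, MV = mv,
             rise_time = rise, quadriceps_strength = strength)
}

#' Closed-form population correlations of the cohort model
#'
#' For an outcome y = a + b * x + e with independent noise,
#' r(x, y) = b * sd(x) / sqrt(b^2 sd(x)^2 + sd(e)^2); chained outcomes
#' multiply correlations because the noises are independent. Ages are
#' uniform, so sd(age) = range / sqrt(12). (The simulated IMAT% is floored at
#' zero; with the default parameters the floor is hit with negligible
#' probability, so the closed forms are exact to working accuracy.)
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @return Named numeric vector of population correlations.
#' @export
cohort_expected_correlations <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  sd_age <- diff(spec$age_range) / sqrt(12)
  r_of <- function(b, sd_x, sd_e) b * sd_x / sqrt(b^2 * sd_x^2 + sd_e^2)
  r_age_md <- r_of(spec$md_age_slope, sd_age, spec$noise_sds$md)
  r_age_imat <- r_of(spec$imat_age_slope, sd_age, spec$noise_sds$imat)
  r_age_mv <- r_of(spec$mv_age_slope, sd_age, spec$noise_sds$mv)
  sd_imat <- sqrt((spec$imat_age_slope * sd_age)^2 + spec$noise_sds$imat^2)
  sd_md <- sqrt((spec$md_age_slope * sd_age)^2 + spec$noise_sds$md^2)
  r_imat_rise <- r_of(spec$rise_imat_slope, sd_imat, spec$noise_sds$rise)
  r_md_strength <- r_of(spec$strength_md_slope, sd_md, spec$noise_sds$strength)
  c(age_MD = r_age_md,
    age_IMAT_pct = r_age_imat,
    age_MV = r_age_mv,
    MD_IMAT_pct = r_age_md * r_age_imat,
    IMAT_pct_rise_time = r_imat_rise,
    MD_quadriceps_strength = r_md_strength,
    age_rise_time = r_age_imat * r_imat_rise,
    age_quadriceps_strength = r_age_md * r_md_strength)
}
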