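---
title: "Quantifying intramuscular adipose tissue from CT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intramuscular adipose tissue from CT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imatct)
```

## The measurement problem

Myosteatosis — fat infiltration of skeletal muscle — accompanies sarcopenia
and degrades muscle quality before muscle volume visibly changes. On a
calibrated CT scan, fat and lean muscle separate by attenuation, so two
quantities summarise muscle quality: the mean attenuation over a muscle
region of interest (muscle density, MD) and the volume fraction of voxels
falling in a fat band inside that region (IMAT%). `imatct` implements this
measurement for two acquisition settings: ex-vivo micro-CT of small-animal
muscle at 8.4 µm voxels, and in-vivo HR-pQCT of the human distal leg at
82 µm voxels.

The pipeline is deliberately simple and fully deterministic: every stage is
a morphological or band-threshold operation with explicit constants, so a
run is reproducible from its configuration alone (`run_imat()` records a
hash of the effective configuration with every output).

## Pipeline stages and their parameters

1. **Denoising.** A separable truncated Gaussian, σ = 2.5 voxels with
   support (truncation radius) 5, i.e. 11-tap axis kernels renormalised to
   unit sum. Borders are mirror-reflected with the edge sample repeated;
   constants therefore pass through unchanged. The σ/support pair follows
   the scanner vendor's convention for these protocols; the reflection
   policy is our choice (the vendor's is undocumented) and avoids biasing
   attenuation at the skin–air interface.
2. **Downscaling (human workflow).** Non-overlapping 2³ block means take
   82 µm data to the 164 µm working resolution; trailing voxels that do not
   fill a block are dropped. Filtering happens at the native resolution
   *before* downscaling — the evaluation software applies its Gaussian to
   the native reconstruction, and the order matters: filtering at the
   working grid instead would double the physical blur and visibly
   under-detect fat structures near the resolution limit.
3. **Bone exclusion.** Voxels ≥ 600 HU, component-filtered (≥ 27 voxels)
   and closed with radius 1 to bridge trabecular gaps. The closing erodes
   with a foreground border so a bone column spanning the stack keeps its
   end slices.
4. **Skin exclusion.** Exterior air is the border-connected component of
   voxels ≤ −800 HU (only the transverse faces count as "outside"; the
   stack runs through its axial extent). The skin shell is everything
   within 4 voxels of exterior air, found by iterative restricted dilation.
   Internal air pockets are not exterior by construction.
5. **Seeding and region growing.** Seeds are the closed-interval threshold
   masks (muscle 100–600 HU, fat −600…−200 HU) eroded once, with components
   below 27 voxels discarded. Exactly 20 growth rounds follow; in each
   round every unassigned soft-tissue voxel adjacent (6-connectivity) to a
   region whose relaxed band (± 100 HU) contains its value joins that
   region. A voxel reachable by both regions in the same round goes to the
   nearer nominal band midpoint, ties to muscle. The update is computed for
   all voxels simultaneously, so the result cannot depend on traversal
   order — that determinism is a contract, tested by comparing against a
   breadth-first flood-fill oracle.
6. **Muscle ROI.** The grown muscle label is smoothed into the
   muscle-envelope contour. The default takes the slice-wise convex hull
   (`roi_method = "hull"`): the fascial envelope of a distal-leg cross
   section is nearly convex, and the hull keeps fat pockets that open onto
   the muscle boundary inside the ROI, where anatomically they belong
   (the deep fascia, not the pocket mouth, bounds the compartment). For
   markedly concave anatomy a slice-wise morphological closing
   (`roi_method = "close"`, radius 14 voxels ≈ 2.3 mm at 164 µm) is
   available instead. Enclosed holes are filled (transverse faces only)
   and bone/skin/air removed.
7. **Peeling and IMAT.** The ROI is eroded 3 times with the 6-connected
   element, discarding the partial-volume rim. IMAT is the closed fat band
   intersected with the peeled ROI: −600…100 HU for micro-CT, −600…−20 HU
   for HR-pQCT. The human upper threshold is lower because partial-volume
   mixing at 82 µm lifts fat–muscle boundary voxels above the ex-vivo
   cutoff; one printed occurrence of "−20 to 100 HU" for this band is
   inconsistent with the three other statements of −600…−20 and is treated
   as an erratum, though that band remains reachable through
   `imat_config("custom")`.
8. **Metrics.** Volumes are voxel counts × voxel volume. MD is the mean
   attenuation over the peeled ROI *including* IMAT voxels — MD and IMAT%
   are two characteristics of one ROI — with a lean-only density reported
   alongside. IMAT% uses the peeled ROI volume as denominator; IMAT/MV uses
   the lean volume, making the two ratios genuinely different summaries.
   MCSA is MV divided by the scanned stack height. An empty ROI yields
   `NA` metrics rather than divisions by zero.

All constants above live in `segmentation_config()` / `imat_config()` /
`filter_spec()`; the two workflow presets (`run_config("microCT")`,
`run_config("HRpQCT")`) differ only in data, not code paths.

## The phantom: what it emulates, and what it does not

`generate_ct_phantom()` builds a leg cross-section as concentric cylinders —
cortical bone core (1500 HU), muscle annulus (300 HU), subcutaneous fat ring
(−400 HU), skin shell (0 HU), exterior air (−1000 HU) — at the native
protocol geometry (256 × 256 × 110 voxels, 82 µm, the clinical slice count),
with i.i.d. Gaussian HU noise. Tissue means sit mid-band on the protocol's
own scale, which is a vendor-specific HU-like calibration: its muscle band
(100–600 HU) lies far above diagnostic-CT muscle attenuation (~50 HU), so
the phantom adopts the protocol's scale without asserting it equals clinical
HU.

IMAT inclusions are prolate ellipsoids elongated along the slice axis
(transverse semi-axes 8–11 voxels ≈ 0.7–0.9 mm, axial 16–22 voxels), since
fat streaks follow the muscle fibre direction. Three design decisions
matter for interpretation:

* **Size.** Inclusions must be resolvable after the σ = 2.5 filter. A
  164 µm-scale sphere of 3-voxel radius blurs to about +111 HU at its
  centre — outside *every* fat band — so structures at that scale are
  invisible to the protocol itself. The defaults sit comfortably above this
  limit; recovery results therefore speak to the protocol's behaviour on
  resolvable fat, not to its (genuinely poor) sensitivity to finely
  dispersed lipid.
* **Placement.** Centers are sampled uniformly over the compartment's
  expanded bounding box and inclusions are clipped to the compartment.
  Sampling centers only inside the compartment would leave a depleted
  boundary layer (coverage ramps from ρ/2 at the boundary to ρ one radius
  in), and a peeled-ROI estimate would then systematically overshoot the
  compartment-wide true fraction. With expanded-center sampling the
  expected fat density is spatially uniform, which is the property that
  makes "density of the peeled interior" an unbiased estimate of
  "fraction of the whole compartment".
* **Truth bookkeeping.** The ground-truth muscle label covers the whole
  compartment (inclusions included, matching the contour sense of the ROI);
  the IMAT truth is a separate mask; the true fraction is IMAT voxels over
  compartment voxels, achieved to within 0.002 by rejection sampling with
  small top-off inclusions near the target.

What the phantom does **not** emulate: partial-volume physics beyond
voxelisation, beam hardening and ring artefacts, motion, anatomical shape
variation (the muscle envelope is exactly convex, so the hull ROI is exact
by construction — on real concave anatomy the hull would over-claim and the
closing variant is the safer choice), fascia and intermuscular septa
(an optional fat-free fascia shell exists but is off by default), and any
correlation between noise and tissue. Passing the recovery grid therefore
shows the pipeline's stages compose correctly and recover known truth under
the protocol's own smoothing and thresholds — not that the thresholds are
biologically optimal on patient data.

`run_phantom_validation()` runs the full grid — true fractions
{0, 5, 10, 20}% × noise {0, 30, 50} HU — through the complete workflow and
reports truth, estimate, error and the Dice overlap of the recovered ROI
against the ground-truth compartment (block-majority downsampled to the
working grid). The companion stained-image generator writes ORO fixtures
whose positive-pixel count is exact by construction (colours are sampled
strictly inside/outside the HSB bands with a quantisation guard band and
verified pixel-by-pixel), so the histology quantifier can be tested against
an exact truth.

## The cohort simulator

`generate_cohort()` draws ages uniformly on 18–81 years and builds outcomes
by a linear-Gaussian chain: MD declines with age (−1.5 HU/yr), IMAT% rises
(+0.15 %/yr), muscle volume declines, chair-rise time increases with IMAT%,
and quadriceps strength increases with MD, each with independent Gaussian
noise. Every population correlation then has a closed form
(`cohort_expected_correlations()`): for y = a + bx + ε,
r = b·sd(x)/√(b²sd(x)² + σ²), and chained pairs multiply. The default noise
scales are set so the key population correlations sit near the magnitudes
reported for human ageing cohorts (age–MD ≈ −0.76, age–IMAT% ≈ +0.56,
IMAT%–rise time ≈ +0.67, MD–strength ≈ +0.59). One structural consequence
of the chain: the MD–IMAT% correlation is induced entirely through shared
age, so its magnitude is the product of the two age correlations (≈ −0.43)
rather than an independently tunable value — the simulator reproduces the
sign structure of the reported table, not every pairwise magnitude.

## Statistical layer

Pearson r with the textbook two-tailed t transform, simple least squares
with the R² = r² identity, pooled-variance Student's t (not Welch — the
original comparisons assume equal variances), and the two-sided
normal-approximation sample size n = ⌈2(z₁₋α/₂ + z_power)²(σ/δ)²⌉, which is
the only reading under which a 30-unit difference with σ = 15 at 80% power
and α = 0.05 gives 4 per group; the exact noncentral-t solution
(`method = "exact"`) is provided and gives a larger n. Correlation tables
flag p < 0.05 and p < 0.01 without multiple-testing correction, matching the
single-test star convention of the original tables; a Benjamini–Hochberg
option exists and is off by default.

A note on validating the t-test against an exhaustive 4-vs-4 permutation
oracle: C(8,4) = 70 relabelings give the oracle a resolution of 1/70 and a
two-sided floor of 2/70 ≈ 0.029, so agreement within 0.02 is only a
meaningful check on fixtures whose permutation distribution brackets the
observed statistic smoothly; the test suite uses designed fixtures in that
regime.

## Numerical conventions

* All thresholds are closed intervals (lo ≤ x ≤ hi), matching the inclusive
  "lower/upper threshold" usage; tested against per-voxel loops.
* Erosion treats the array exterior as background (border voxels peel away)
  except inside closings, where a foreground border preserves structures
  that span the stack.
* Connected components (igraph over the voxel adjacency graph) are labelled
  by smallest contained voxel index, so labels are deterministic.
* Hue is on the ImageJ 0–255 scale, rounded from degrees; the ORO hue band
  does not wrap, and a wrap-around option exists for other stains.
* HU is the canonical internal unit; conversion to hydroxyapatite-equivalent
  density is exposed as an optional linear map with no default constants,
  because those are scanner calibration data.

## Problem sizes

The validation grid uses 256 × 256 × 110 phantoms at 82 µm (the clinical
protocol geometry), downscaled to 128 × 128 × 55 for analysis; the cohort
checks use n = 5000; oracle equivalences run on ≤ 32³ volumes where
brute-force references are exact. These sizes keep the full validation
suite in the low minutes on a single CPU while exercising every stage at
the protocol's own scale.

## Known limitations

* The vendor's Soft Tissue Analysis algorithm is proprietary; this is a
  documented approximation sharing its stated knobs (bands, 20 iterations,
  seed planting). Unstated constants are explicit configuration defaults,
  not recovered vendor values.
* IMAT recovery degrades for fat structures near the filter scale, and the
  protocol underestimates finely dispersed lipid by construction; the
  histology route exists precisely because CT misses sub-resolution fat.
* The hull ROI assumes a convex muscle envelope; use the closing variant
  for anatomy where that fails.
* Scanner physics (beam hardening, motion) and inter-muscular (between
  muscle group) fat are out of scope.
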