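# imatct

Quantification of intramuscular adipose tissue (IMAT) in calibrated CT
volumes of skeletal muscle, for researchers studying myosteatosis and
sarcopenia with ex-vivo micro-CT (8.4 µm) or in-vivo HR-pQCT (82 µm)
imaging. The package implements the full analysis chain — Gaussian
denoising, Hounsfield-unit band thresholding, bone/skin exclusion, seeded
region growing of the soft-tissue compartments, morphological peeling of the
muscle ROI, and IMAT segmentation — together with an Oil-Red-O histology
quantifier, synthetic phantoms with known ground truth, and the statistical
layer used to relate the imaging metrics to age and muscle function.

## Method

A calibrated volume (HU; air ≈ −1000, water ≈ 0) is smoothed with a
truncated separable Gaussian (σ = 2.5 voxels, support 5) and, in the human
workflow, block-averaged from 82 µm to 164 µm. Bone (≥ 600 HU) and a
peripheral skin shell are excluded; seed volumes are planted by closed-band
thresholds (muscle 100–600 HU, fat −600…−200 HU) and grown for 20 iterations
into band-eligible neighbours. The muscle label is smoothed into the
muscle-envelope ROI (slice-wise convex hull by default), peeled by 3 voxels
to suppress partial-volume borders, and IMAT is segmented inside it by a
fat band (micro-CT preset −600…100 HU; HR-pQCT preset −600…−20 HU). Reported
metrics:

* `MV` (mm³) — peeled muscle ROI volume; `TV` — total soft-tissue volume
* `MD` (HU) — mean attenuation over the peeled ROI (IMAT included), a
  lean-quality surrogate; `FD` — mean attenuation of subcutaneous fat
* `IMAT.V` (mm³), `IMAT% = 100·IMAT.V/MV`, `IMAT/MV = IMAT.V/(MV − IMAT.V)`
* `MCSA` (mm²) — `MV` divided by the scanned stack height

Histology: Oil-Red-O positive area by fixed HSB thresholds (hue 228–255,
saturation 167–255, brightness 0–255 on the ImageJ 0–255 scale), averaged
over four images per specimen. Statistics: Pearson r with two-tailed p,
simple regression R², pooled-variance Student's t, and the two-sided
normal-approximation sample-size formula
n = ⌈2·(z₁₋α/₂ + z_power)²·(σ/δ)²⌉.

## Worked example

```r
library(imatct)

# a synthetic leg at native 82 um with 10% intramuscular fat
ph  <- generate_ct_phantom(phantom_spec(fat_fraction = 0.10, rng_seed = 42))
run <- run_imat(ph$volume, run_config("HRpQCT"), specimen_id = "phantom42")
print(run$metrics)
```

```
soft_tissue_metrics (HRpQCT preset)
  TV         1924.94 mm^3
  MV          709.52 mm^3   MV/TV 0.369
  MD           225.8 HU     (lean-only 281.1 HU)
  FD          -367.8 HU
  IMAT.V       73.74 mm^3   IMAT% 10.39   IMAT/MV 0.1160
  MCSA         78.66 mm^2 over 9.02 mm stack
```

The phantom's true fat fraction was 10.05%, recovered as IMAT% 10.39 — within
the ±2 percentage-point validation band. `MD` sits below the 300 HU muscle
mean because fat voxels inside the ROI pull the mean attenuation down;
the lean-only density (281 HU) is reported alongside.

```r
g <- generate_oro_image(0.075, rng_seed = 42)   # stained image, 7.5% positive
area_fraction(oro_positive_mask(g$image, hsb_threshold()))
#> [1] 7.5

sample_size_normal(delta = 30, sd = 15, power = 0.80, alpha = 0.05)
#> [1] 4
```

A command-line front end is installed with the package
(`system.file("cli", "imatct", package = "imatct")`) with subcommands
`imat`, `oro`, `phantom`, `validate` and `cohort-stats`.

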