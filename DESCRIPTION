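Package: imatct
Title: Intramuscular Adipose Tissue Quantification from CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segmentation of skeletal muscle and quantification of
    intramuscular adipose tissue (IMAT) in calibrated micro-CT and HR-pQCT
    volumes: Gaussian denoising, Hounsfield-unit band thresholding, bone and
    skin exclusion, seeded region growing, morphological ROI peeling, and
    the derived soft-tissue metrics (muscle volume and density, IMAT volume
    and percentage, cross-sectional area). Includes an Oil-Red-O histology
    positive-area quantifier by fixed HSB colour thresholding, synthetic leg
    phantoms and stained-image generators with known ground truth for
    validation, and the statistical layer used to relate imaging metrics to
    age and functional outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    igraph,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
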