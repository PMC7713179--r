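Package: maraq
Title: Threshold-Based Quantification of Metal Artifacts in CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semi-automated quantification of metal artifacts in computed
    tomography volumes using reference-region statistics and mean +/- k*SD
    Hounsfield-unit thresholds. Computes material thresholds from artifact-free
    reference segmentations, segments out-of-range voxels within propagated
    volumes of interest, applies a misclassification correction factor, and
    reports artifact percentages, image noise and contrast-to-noise ratios per
    acquisition series. Includes a synthetic hip-prosthesis phantom generator
    (tapered metal stem in a foam femur model inside a water bath, with
    distance-decaying streak artifacts and acquisition-mode-dependent Gaussian
    noise) so the complete pipeline can be exercised and validated without
    scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
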