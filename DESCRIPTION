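Package: triseg
Title: Triplanar Consensus U-Net Segmentation for Volumetric MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Volumetric segmentation toolkit built around a single 2D U-Net
    trained on axial, sagittal and coronal slices of isotropically resampled
    head MRI, with fivefold cross-validated training, validation-IoU-weighted
    fold ensembling, and four orientation-fusion strategies (softmax
    averaging, union, majority and unanimous voting). Includes a synthetic
    head/tongue phantom generator with exact ground-truth masks, the full
    preprocessing chain (isotropic resampling, landmark-centered
    reorientation, cohort z-score intensity normalization, segmentation-grid
    cropping), voxel-level evaluation metrics (confusion counts, precision,
    recall, Dice, IoU), tongue-volume quantification in cubic centimeters,
    and Shapiro-Wilk-gated paired and two-group statistical comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    png,
    withr
Config/testthat/edition: 3
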