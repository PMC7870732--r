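Package: lbmct
Title: Lean Body Mass from Limited-Coverage CT and PERCIST Response Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates patient-specific lean body mass (LBM) from the fat volume
    measured on the limited-coverage CT of a routine PET/CT examination, and
    quantifies how the choice of LBM algorithm (predictive equation versus
    CT-derived) changes PERCIST 1.0 treatment-response classifications.
    Provides Hounsfield-unit fat segmentation and volumetry on voxel volumes
    (NIfTI and DICOM series input), the James predictive equation, fitting of
    the limited-coverage fat-volume to whole-body fat-mass regression, SUL
    computation and PERCIST classification (adaptive lesion segmentation,
    SUL peak, measurability rules, response classes), concordance statistics
    (Cohen's kappa, Wilcoxon signed-rank on ordinal classes, paired t,
    Bland-Altman, threshold-band discordance), and synthetic generators for
    voxel phantoms and cohorts with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
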