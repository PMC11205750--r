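Package: radiogam
Title: Voxel-Wise Prediction of Glioma Mutation Status from
    Multiparametric MRI with Boosted Additive Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for voxel-wise radiogenomic analysis of glioma:
    stereotactic-biopsy sphere regions of interest with normal-appearing
    white matter (NAWM) signal normalization, a gradient-boosted
    generalized additive model built from per-feature decision stumps
    (univariate shape functions), and leave-one-patient-out ROC/AUC
    evaluation with standard-error bands across all contrast
    combinations.  Includes a seeded synthetic multiparametric MRI
    cohort generator with planted, recoverable effect sizes so the full
    pipeline can be exercised and calibrated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tools,
    graphics,
    grDevices,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
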