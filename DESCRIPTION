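Package: dosurv
Title: Dosiomics and Survival Modelling of Late Cardiac Disease after
    Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end survival-dosiomics analysis for late severe cardiac
    disease after childhood-cancer radiotherapy: summation and outlier
    clipping of per-session 3D dose volumes, extraction of dose-volume
    indicators, first-order statistics and gray-level texture features
    (GLCM, GLRLM, GLSZM, NGTDM, GLDM) over the heart and its subparts,
    association and redundancy screening of predictors, four survival
    models (Cox proportional hazards, Cox Lasso with the one-standard-error
    rule, Cox bootstrap Lasso stability selection, random survival
    forests), and censoring-aware prediction-error estimation (Harrell and
    inverse-probability-of-censoring-weighted concordance, Brier score and
    its integral) with stratified cross-validation and bootstrap
    out-of-bag error curves. A seeded synthetic cohort generator with
    heavy right censoring emulates the statistical structure of such
    cohorts so the full pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    Rcpp,
    rlang,
    RNifti,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
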