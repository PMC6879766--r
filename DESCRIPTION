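Package: cardioahi
Title: Apnea-Hypopnea Index Estimation from ECG-Derived Cardiovascular Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the apnea-hypopnea index (AHI) from single-lead ECG or
    inter-beat-interval series. Implements respiratory-event epoch labelling on
    the 30-second grid, heart-rate-variability feature extraction with window and
    coverage rules, greedy transformation-chain optimisation of feature
    separability, imbalanced epoch classification with SMOTE and edited
    nearest-neighbour cleaning, robust Theil-Sen calibration of the epoch-ratio
    to events per hour, OSA severity grading, and the agreement and screening
    evaluation toolkit (Bland-Altman, Cohen's kappa, ROC). A synthetic-recording
    generator with known ground-truth AHI supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    lmtest,
    MASS,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    optparse,
    pROC,
    readr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
LinkingTo:
    Rcpp
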