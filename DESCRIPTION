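Package: akiward
Title: Real-Time Prediction of Acute Kidney Injury on Inpatient Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for real-time acute kidney
    injury (AKI) risk modeling from longitudinal inpatient data: KDIGO
    creatinine-criteria AKI detection on irregularly sampled series,
    discrete-time observation-row construction with carry-forward covariates
    and 24-hour-lookahead labels, covariate-class logistic hazard models with
    patient-clustered sandwich inference, and cluster-aware ROC/AUC
    evaluation with operating-point planning. Includes a synthetic
    electronic-health-record generator with a known discrete-time logistic
    hazard so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    knitr,
    pROC,
    rmarkdown,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
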