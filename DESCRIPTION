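Package: icutraj
Title: ICU Mortality Models from Clinical Trajectories and Note Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and validates in-hospital mortality prediction models for
    intensive care unit (ICU) admissions from the first 24 hours of
    electronic health record data. Provides a multi-site synthetic EHR
    cohort generator (irregularly sampled labs and vitals with
    outcome-dependent trends, outcome- and site-conditioned note term
    frequencies, early deaths); cohort selection and 24-hour windowing;
    trajectory feature engineering (min, max, mean, SD, first, last,
    last-minus-first, least-squares slope) with train-only median
    imputation; sublinear TF-IDF text featurization over per-site top-k
    vocabularies; L2-penalized logistic regression fit by iteratively
    reweighted least squares with inner cross-validated penalty selection;
    discrimination (AUC, AUPRC), modified Hosmer-Lemeshow calibration,
    cut-point metrics and bootstrap confidence intervals; and a validation
    harness running repeated nested 10-fold cross-validation, a cross-site
    train/test transfer matrix, an alive-at-24-hours sensitivity analysis,
    and construct-validity comparisons of trajectory measures between
    survivors and nonsurvivors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
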