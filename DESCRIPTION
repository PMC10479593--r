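Package: calibra
Title: Literature-Based Naive-Bayes Cardiovascular Risk Prediction for
    Chronic Kidney Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compiles published effect sizes (odds, risk and hazard ratios)
    into a naive-Bayes network predicting the one-year risk of cardiovascular
    hospitalization in non-dialysis-dependent chronic kidney disease.
    Effect sizes are pooled by sample-size-weighted fixed-effect
    meta-analysis and inverted into conditional probability tables given
    outcome and exposure prevalences. Patients are scored under arbitrary
    missing data by exact naive-Bayes marginalization; per-evidence impact
    (normalized likelihood) and value-of-information (conditional mutual
    information) metrics explain each score. Includes equation-based
    comparator scores in Cox form, ROC/AUC evaluation with DeLong paired
    comparison and a fixed-order non-inferiority/superiority procedure,
    quantile calibration tables, exact Poisson incidence densities, and a
    synthetic-cohort simulator with configurable missingness.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
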