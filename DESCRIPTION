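Package: lashape
Title: Left Atrial Shape Metrics and Discriminant Stroke-Risk Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes left atrial (LA) shape statistics (sphericity and
    volume coefficient) from six center-of-mass radial measurements taken
    along the three principal axes of the atrium, scores patients with a
    published eight-coefficient linear discriminant for prior-stroke risk
    in atrial fibrillation, re-fits two-class linear discriminants with
    leave-one-out cross-validated misclassification estimates, and runs
    the accompanying statistical battery: two-group tests from raw data or
    printed summaries, categorical tests, logistic regression, ROC/AUC
    with DeLong confidence intervals, tertile analysis, CHA2DS2-VASc and
    HAS-BLED scoring, and combination of an imaging score with a clinical
    risk score. Includes a seeded synthetic case-control cohort generator
    calibrated so that simulated sphericity matches configured targets,
    and an end-to-end analysis pipeline that emits machine-readable
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    pROC,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
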