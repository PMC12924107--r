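Package: lapscore
Title: Preoperative Difficulty Scoring and Diagnostic Validation for
    Laparoscopic Cholecystectomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a nine-parameter preoperative scoring system for
    predicting difficult laparoscopic cholecystectomy, an intraoperative
    difficulty grading scheme (operative time, bile or stone spillage,
    duct or artery injury, conversion to open surgery), and the complete
    diagnostic-validation pipeline used to evaluate such scores: exact and
    asymptotic contingency-table tests (Fisher, Freeman-Halton,
    chi-square), Mann-Whitney and t comparisons, Spearman correlation,
    sensitivity/specificity/PPV/NPV with Clopper-Pearson exact confidence
    intervals, ROC curves with trapezoidal AUC and DeLong variance,
    Youden-index cutoff selection, confusion-table reconstruction from
    rounded published metrics, Buderer sample-size calculations, and
    univariate/multivariate logistic regression fitted by iteratively
    reweighted least squares with separation diagnostics. A configurable
    synthetic-cohort generator reproduces the marginal prevalences of a
    150-patient elective cholecystectomy cohort so that every stage of the
    pipeline can be exercised without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
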