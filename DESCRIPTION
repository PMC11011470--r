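Package: triagecut
Title: Threshold Policies and Workload Estimation for Multi-Label
    Radiograph Triage Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Evaluation pipeline for multi-label diagnostic AI scores on
    chest radiographs. Builds empirical ROC curves per abnormality, selects
    operating cutoffs either by maximizing Youden's J or by enforcing a
    minimum sensitivity, derives confusion counts and the standard
    diagnostic metrics (sensitivity, specificity, PPV, NPV, FPR) with both
    arithmetic and pooled cross-entity averages, applies a conservative
    patient-level classification for simultaneous reading of all
    abnormalities with workload-reduction estimates, and fits a blockwise
    linear regression of score-to-gold-standard deviation on patient
    covariates. Includes a seeded synthetic cohort generator calibrated to
    published summary statistics (prevalences, finding multiplicity, score
    distributions, covariates) so the whole pipeline runs without access to
    the original patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    sandwich
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
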