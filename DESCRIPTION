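Package: riskrules
Title: Decision-Rules Risk Stratification for Cardiometabolic Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements three decision-rules classifiers that stratify
    individuals into four ordinal risk categories (clinical, high, elevated,
    not elevated) for incident coronary artery disease, type 2 diabetes, and
    hypertension, combining blood biomarkers, physical measurements,
    Framingham risk categories, family history, and polygenic risk score
    deciles. Includes additive polygenic scoring with imputation-quality
    filtering and covariate adjustment, baseline eligibility exclusions, a
    synthetic-cohort generator with proportional-hazards incident events, and
    a full evaluation layer: confusion counts at the advised-intervention
    dichotomy, sensitivity and specificity, bootstrap AUROC, DeLong
    comparison of correlated ROC curves, the Net Reclassification Index, and
    Cox proportional-hazards hazard ratios per risk stratum.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
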