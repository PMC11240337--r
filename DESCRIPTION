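Package: uevpanel
Title: Urinary Extracellular Vesicle Transcript Panels for Active
    Surveillance Risk Reclassification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reanalysis pipeline for predicting prostate-cancer risk
    reclassification on active surveillance from urinary extracellular
    vesicle (uEV) transcript markers and clinical indices. Implements
    qPCR crossing-point quantification by the delta-delta-CP method with
    reference-gene geometric-mean normalization, clinical index
    derivation (PSA density, PSA velocity, reclassification labelling),
    ROC analysis with DeLong inference and Youden-index cutoff
    optimization, 2x2 diagnostic accuracy statistics and odds ratios,
    univariate and forward-stepwise logistic predictor selection, binary
    risk-factor sum scores (2C-, 3T-, 2C-3T-Score) with biopsy-avoidance
    summaries, cohort comparison tables, and a synthetic cohort
    generator emulating the study conditions for end-to-end testing.
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
    pROC
Config/testthat/edition: 3
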