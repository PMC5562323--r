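Package: phscreen
Title: Noninvasive Serum Fibrosis Indexes for Portal Hypertension Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes seven serum liver-fibrosis indexes (AAR, APRI, FI,
    FIB-4, King's score, Forns index, Lok index) and evaluates them as
    noninvasive predictors of portal hypertension graded by the hepatic
    venous pressure gradient (HVPG). Provides empirical ROC analysis with
    Hanley-McNeil standard errors, Youden-index cutoff selection and
    placement-based paired AUC comparison; full diagnostic-metric panels
    (sensitivity, specificity, predictive values, likelihood ratios,
    accuracy) with exact binomial confidence intervals; a dual-index
    screening rule with agreement statistics; a proportional-odds ordinal
    model of HVPG grade on serum markers; and a calibrated synthetic
    cirrhosis-cohort generator for end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), MASS, pROC, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
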