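Package: ckdscore
Title: Points-Based Risk Scoring for Chronic Kidney Disease in Type 2 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derivation and validation pipeline for a Framingham-style integer
    points score predicting 3-, 5- and 10-year risk of chronic kidney disease
    (CKD) among adults with type 2 diabetes. Includes a seeded synthetic-cohort
    generator (Weibull proportional-hazards event process, first-year fasting
    plasma glucose series), clinical derivations (MDRD-type estimated
    glomerular filtration rate, visit-adjusted glucose coefficient of
    variation, CKD classification, incidence rates), Cox model fitting with
    two-stage backward-elimination variable selection, conversion of the
    fitted model into an integer score sheet and point-total risk table, and
    evaluation by horizon ROC/AUC, Hosmer-Lemeshow calibration and
    observed-versus-predicted deciles.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
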