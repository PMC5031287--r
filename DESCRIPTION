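Package: riskstratsim
Title: Simulation of Risk Stratification Capacity of Clinical Prediction Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study how the prevalence and strength of association
    of candidate predictors determine the clinical usefulness of logistic
    risk prediction models. Generates a calibrated synthetic obstetric
    cohort (preeclampsia among overweight/obese women; 8.4% incidence,
    baseline AUC 0.68), injects binary predictors with exact target
    marginal prevalence and univariable odds ratio, refits logistic
    models, and evaluates discrimination (AUC with bootstrap optimism
    correction), risk stratification capacity at clinical thresholds,
    stratum likelihood ratios, calibration (Hosmer-Lemeshow), and
    Nagelkerke's pseudo R-squared across a factorial grid of predictor
    characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
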