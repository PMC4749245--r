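Package: amsaShock
Title: Defibrillation Outcome Prediction from VF Waveform and Previous-Shock Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies pre-shock ventricular fibrillation (VF) waveforms with
    the amplitude spectrum area (AMSA), derives within-patient previous-shock
    features (previous shock index, change in AMSA between consecutive shocks),
    and combines them with a small regularized feed-forward network or a
    random-intercept logistic model to predict defibrillation success.
    Includes a calibrated synthetic cohort generator, ROC evaluation at a
    fixed-specificity operating point, paired AUC comparison for correlated
    ROC curves, and an end-to-end reproducible experiment pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    survival,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
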