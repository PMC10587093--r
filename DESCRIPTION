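Package: evpanel
Title: Development and Validation of Blood EV-Protein Biomarker Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing diagnostic classifiers from multiplex
    extracellular-vesicle (EV) protein panels measured in blood. Covers the
    full pipeline used for early-detection biomarker tests: lower limit of
    detection (LLoD) imputation of left-censored immunoassay concentrations,
    reliability and correlation/Kolmogorov-Smirnov feature filters, repeated
    stratified cross-validation with leakage-free in-fold filtering driven by
    the partial AUC over the high-specificity band, permutation feature
    importance, recursive feature elimination to a compact log2-scale logistic
    signature, a locked classifier with a specificity-anchored score cutoff,
    Wilson and bootstrap confidence intervals, and a measurement-noise
    perturbation robustness study based on within-patient coefficients of
    variation. Includes a synthetic case/control cohort generator emulating
    censored, correlated log-normal immunoassay panels so every stage is
    testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    ranger,
    xgboost,
    e1071,
    withr
Config/testthat/edition: 3
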