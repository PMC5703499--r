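Package: metaboSens
Title: Predicting Sire-Family Heat-Stress Sensitivity from Plasma NMR
    Metabolomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the sensitivity of pig sire families to chronic
    heat stress from phenotypes recorded in temperate and tropical
    environments, and predicts that sensitivity from plasma 1H-NMR
    bucket-table metabolomes collected under thermoneutral conditions.
    Provides empirical-Bayes batch/sex adjustment with principal variance
    component analysis diagnostics, a composite Welch-t/PCA sensitivity
    index, a sparse PLS-DA classifier with soft-threshold variable
    selection, cross-validated balanced error rate, VIP scores and
    selection-stability frequencies, family membership rates, and a
    synthetic study generator emulating the design for testing and
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    sva,
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
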