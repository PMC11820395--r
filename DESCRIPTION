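Package: sebumetrics
Title: Reproducibility and Classification of Groomed-Fingerprint Sebum Lipid Profiles
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Workflow for flow-injection ESI-MS lipidomics of groomed latent
    fingerprints: reads centroided MS1 (text) and mzML spectra, sums peak
    intensities into 0.01 Da m/z bins over a fixed retention-time window to
    build a bins-by-samples feature matrix, applies sparse-bin filtering,
    total-ion-current normalization, shifted log2 transformation, per-feature
    batch correction and top-median feature selection, and evaluates the
    resulting profiles by intra-/inter-batch percent relative standard
    deviation and by donor-exclusion leave-one-out classification with
    gradient-boosted trees (ROC/AUC) and principal component analysis with
    group concentration ellipses. Includes a synthetic cohort generator that
    emulates the statistical structure of a multi-donor fingerprint study so
    every stage is testable without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    limma,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    mzR,
    pROC,
    ggplot2,
    withr
Config/testthat/edition: 3
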