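Package: ramanbc
Title: Blood-Plasma Raman Spectral Pipeline for Early Breast-Cancer
    Subtype Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end chemometric analysis of blood-plasma Raman spectra
    for stage-Ia breast-cancer subtype classification. Implements spectral
    preprocessing (PCA-score outlier rejection, rolling-ball baseline
    correction, global standardization, modified-z cosmic-ray despiking,
    Whittaker smoothing), PCA-LDA classification with leave-one-out
    cross-validation and a frozen-eigenvector validation protocol,
    one-vs-rest micro/macro ROC analysis, per-wavenumber Mann-Whitney
    difference-spectrum statistics with band annotation, complete-linkage
    hierarchical clustering of discriminant coordinates, and a synthetic
    plasma-spectrum generator that emulates the statistical structure of
    the study design so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    ape,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
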