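Package: rpstack
Title: Random-Projection Stacking for Expression-Based Subtype Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies tumour subtypes from high-dimensional expression
    profiles by fusing multiple independent Gaussian random projections and
    stacking a heterogeneous panel of base classifiers under a multilayer
    perceptron meta-learner. Includes TPM/log preprocessing for expression
    matrices, Johnson-Lindenstrauss distance-preservation diagnostics, a
    score-ensemble baseline, repeated stratified cross-validation with
    accuracy/F1/MCC/AUC metrics and paired significance tests, and a seeded
    generator of synthetic two-subtype expression data with co-expressed
    gene blocks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ranger,
    rpart,
    xgboost,
    yaml,
    graphics,
    grDevices,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
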