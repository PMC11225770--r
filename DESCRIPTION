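Package: lionsel
Title: Lion Optimization Wrapper Feature Selection for Pest Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A from-scratch Lion Optimization Algorithm (LOA) - a pride/nomad
    population metaheuristic with hunting, safe-place, roaming, mating,
    defense, migration and equilibrium operators - used as a binary wrapper
    feature selector over image-derived feature tables, together with the
    classical reducers (PCA, LDA, RFE), image filtering and augmentation,
    a pluggable deep-feature extraction interface with a deterministic mock
    backbone, a seven-classifier bank with accuracy/precision/recall/F1
    reporting under stratified holdout and k-fold protocols, seeded synthetic
    data generators, and an end-to-end pipeline for two-class crop-pest
    image classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    rpart,
    randomForest,
    xgboost,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
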