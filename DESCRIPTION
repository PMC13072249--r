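Package: connsurv
Title: Graph-Theoretical Connectome Features for Survival Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting one-year overall survival from structural
    brain connectomes. Computes global and local graph-theoretical measures
    (binary and weighted) from tract-count and quantitative-anisotropy
    connectivity matrices on a 246-region parcellation, performs two-step
    feature selection (six-filter consensus ranking followed by wrapper
    best-first search) with SMOTE minority oversampling, and runs a
    leakage-safe nested cross-validation over a roster of ten classifier
    families with held-out evaluation. Includes a synthetic cohort generator
    that emulates hub-targeted tumor disruption of block-structured
    connectomes so the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    e1071,
    nnet,
    rpart,
    ranger,
    class,
    jsonlite,
    methods,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pheatmap
Config/testthat/edition: 3
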