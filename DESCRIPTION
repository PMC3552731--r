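Package: wgpr
Title: Whole-Genome Prediction Models, Genome Partitioning and
    Cross-Validated Accuracy for Inbred Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and compares five whole-genome prediction models with
    contrasting shrinkage assumptions (ridge-regression BLUP, LASSO, elastic
    net, reproducing kernel Hilbert space regression on modified Rogers'
    distances, and BayesB with uncertain hyperparameters) on SNP dosage data
    from homozygous inbred line panels. Partitions genetic variance across
    chromosomes by simultaneous multi-kernel REML with principal-component
    correction for population structure, runs a single-marker mixed-model
    association scan, and measures predictive accuracy by repeated five-fold
    cross-validation with heritability correction. Includes a synthetic-data
    generator that emulates a maize-like diversity panel with strong local
    linkage disequilibrium and traits of controlled genetic architecture
    (polygenic or single major QTL), so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
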