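Package: bittersweet
Title: Explainable Bitter/Sweet Taste Classification from 2D Molecular
    Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for binary taste (bitter/sweet)
    classification of small molecules from SMILES strings: structure
    standardization and deduplication, 2D molecular descriptor
    computation, rule-based table cleaning, repeated stratified
    cross-validation over a five-model zoo, variance-corrected resampled
    t-tests for model comparison, a sequential feature-selection
    algorithm combining two-sample Kolmogorov-Smirnov ranking with Ward
    clustering of Spearman correlations, exact and tree-based Shapley
    value explanations, and a Tanimoto-similarity applicability domain.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    xgboost,
    ranger,
    class,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
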