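Package: mhnet
Title: Multi-View Hierarchical High-Order Networks for Functional Connectivity Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds hierarchical multi-scale brain graphs from region-wise
    rs-fMRI-like signals (RV-coefficient connectivity at whole-brain, network
    and regional levels), extracts high-order features with a residual
    Chebyshev spectral graph branch and a 1D-convolutional Euclidean branch,
    and fuses them into a binary classifier of neurodevelopmental disorders.
    Includes threshold (knee-point) selection for graph sparsification, a
    population-graph extension combining learned embeddings with phenotypes
    for transductive classification, a synthetic-cohort generator with planted
    inter-network coupling differences, a cross-validation and ablation
    harness, node-saliency ranking, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tibble,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
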