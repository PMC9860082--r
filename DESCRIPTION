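Package: scwheel
Title: Reference Mapping, Similarity Bands and Wheel Plots for
    Single-Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores the identity quality of stem-cell-derived cultures
    against a labeled single-cell reference atlas. Provides QC filtering
    and log-library-size normalization of UMI count matrices,
    Cytograph-style kNN/Louvain clustering, one-vs-rest L2-regularized
    logistic-regression label transfer with per-cluster similarity bands,
    probability-simplex (wheel) projections, a permutation test on
    gene-panel expression sums, beta-posterior marker-enrichment calls,
    and a negative-binomial synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    graphics,
    grDevices,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
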