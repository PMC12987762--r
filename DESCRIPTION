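Package: coaccess
Title: Cis-Co-Accessibility Network Inference from Single-Cell Chromatin Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts cis-regulatory DNA interactions from single-cell
    ATAC-seq count matrices. Co-accessibility between peak pairs is estimated
    with a graphical lasso carrying an element-wise genomic-distance penalty,
    fitted within sliding windows along each chromosome, with automatic
    calibration of the sparsity parameter. Includes optional LSI-based
    metacell aggregation, extraction of cis-co-accessibility networks (CCANs)
    by Louvain community detection, export of link tables and BEDPE, a
    planted-block synthetic data generator, and evaluation of predicted links
    against chromatin-contact references (promoter capture Hi-C style) via
    ROC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    irlba,
    pROC,
    parallel,
    GenomicRanges,
    IRanges,
    Rcpp,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
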