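Package: epichaos
Title: Cluster-Level Cell-to-Cell Heterogeneity Scores for Single-Cell
    Epigenomics
Version: 0.2.0
Authors@R:
    person("epichaos", "developers", email = "epichaos@example.org",
           role = c("aut", "cre"))
Description: Quantifies cell-to-cell epigenetic heterogeneity within
    clusters or other user-defined groups of cells from binarized
    single-cell epigenomics matrices (scATAC-seq, single-cell DNA
    methylation, scChIP-seq).  Pairwise cell similarities are measured
    with a chance-centered Jaccard index that controls for per-cell
    sparsity, averaged per group, adjusted by regression against the
    mean detected-feature count, and min-max inverted into a relative
    0-1 heterogeneity score.  Includes region-set (TFBS, gene-set
    promoter) scoring, a permutation test for differential
    heterogeneity between two groups, a per-chromosome copy-number
    robust score variant, companion heterogeneity metrics
    (transcriptional noise, DNA methylation variance), synthetic
    benchmark generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    withr,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
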