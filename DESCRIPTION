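Package: chromatlas
Title: Single-Cell Chromatin Accessibility Atlas Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and comparing cell-type-resolved atlases of
    accessible chromatin regions (ACRs) from single-cell ATAC-seq Tn5
    insertion data. Implements per-cell-type pseudobulk peak calling with an
    empirical permutation false discovery rate, entropy-based cell-type
    specificity scoring with a bootstrap significance test, classification
    of H3K27me3-associated broadly accessible candidate silencers and broad
    methylation regions, position-weight-matrix and IUPAC-pattern motif
    scanning with negative-binomial, binomial and hypergeometric enrichment
    tests, a short-word seed-and-extend local aligner with Karlin-Altschul
    E-values for classifying cross-species ACR conservation inside syntenic
    blocks, and dynamic-time-warping alignment of pseudotime motif-deviation
    trajectories between species. A seeded synthetic-data module generates
    every input with planted ground truth so each stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    edgeR,
    limma,
    MASS,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
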