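Package: hdgsnet
Title: Single-Base Nucleosome Occupancy Prediction with Hybrid Dilated,
    Gated and Depthwise-Separable Convolutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts nucleosome occupancy at single-base resolution from DNA
    sequence alone. Implements the HDGS-Net approach: dMean normalization of
    MNase-seq coverage tracks, IQR-based stratified screening of training
    sites, dinucleotide one-hot encoding of 147-bp windows into 16 x 146
    feature matrices, and a hybrid convolutional network combining gated,
    dilated and depthwise-separable 1-D convolutions in three parallel-branch
    modules, trained with Adam on mean squared error. Includes per-chromosome
    evaluation, occupancy-group sequence-composition analyses (quartile,
    k-means and decile groupings with positional dinucleotide frequency
    matrices), strand-aware TSS-centered window construction, and a synthetic
    genome/occupancy simulator so the whole pipeline is testable at desk
    scale. The network runs on the CPU via a compiled float32 implementation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    ggplot2,
    generics,
    Biostrings,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
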