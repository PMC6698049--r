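Package: chromdyn
Title: Chromatin-State Discovery and Butyrate-Induced Dynamics from Epigenomic Marks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns ChromHMM-style chromatin-state segmentations from binarized
    histone-mark, CTCF and ATAC tracks with a multivariate Bernoulli hidden
    Markov model over fixed 200-bp genome windows, and characterizes the
    resulting states: base-level fold enrichment over genomic annotations with
    a log-space Fisher exact test, strand-oriented positional profiles around
    TSS/TES, a circular-permutation marker-set test for GWAS signal
    enrichment, hypergeometric gene-set enrichment, classification of genes by
    promoter-proximal chromatin state, condition-to-condition state-transition
    accounting, a differential-expression filter, and a windowed
    logistic-regression differential-methylation pipeline. Ships a
    deterministic synthetic-data generator emulating a two-condition,
    three-replicate epigenome study so the whole pipeline is testable end to
    end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomeInfoDb,
    ggplot2,
    GenomicRanges,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
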