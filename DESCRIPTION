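Package: pamscape
Title: Target-Site Landscapes, Depletion-Assay Statistics and Base-Editing
    Scope for Palindromic-PAM CRISPR Nucleases
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising CRISPR-Cas9 nucleases with degenerate
    protospacer-adjacent motifs (PAMs), built around the palindromic
    5'-NNTA-3' PAM of FrCas9. Enumerates PAM-adjacent target sites on linear
    and circular genomes, derives back-to-back divergent guide pairs anchored
    on shared TA dinucleotides, and summarises target landscapes (coverage,
    inter-site spacing, dinucleotide spacing, TATA-box targeting). Implements
    statistics for randomised-PAM depletion assays (post-selection PAM
    depletion values, depletion logos, PAM wheels, sgRNA evenness indices,
    GUIDE-seq on:off read ratios), base-editor correctable-variant scoping
    with bystander-aware precision calls and double editing windows, and
    amplicon indel quantification by affine-gap global alignment with
    background subtraction. Ships seed-deterministic synthetic-data
    generators (random genomes, depletion libraries under a hidden PAM rule,
    amplicon read sets with planted indels, variant tables with known
    correctability) so every stage can be exercised against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
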