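Package: egvselect
Title: Partitioned Branch-Site Selection Analysis and Screening of
    Endogenous Geminiviral Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to screen plant genome sequences for endogenous
    geminiviral elements (EGVs) and to test their coding sequences for
    purifying or positive selection. Implements a partitioned branch-site
    random-effects codon model in which every branch-site pair draws its
    dN/dS ratio from a three-category mixture (purifying, neutral,
    positive) whose parameters are shared within branch partitions, with
    MG94-style rates crossed with a general reversible nucleotide model
    and CF3x4 equilibrium frequencies. Provides Felsenstein-pruning
    likelihood evaluation with per-branch mixture transition matrices,
    constrained model fits, chi-squared likelihood-ratio tests for
    selection on foreground partitions, a generative simulator with the
    same branch-site mixture structure, and sequence-screening utilities:
    replication-origin nonanucleotide and stem-loop detection, ORF
    intactness (premature stops, frameshifts), rolling-circle-replication
    motif scans, and conservative distinct-haplotype counting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
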