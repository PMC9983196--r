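Package: astadr
Title: Allele-Specific Contact Domain Analysis for Haplotype-Resolved Hi-C
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects allele-specific topologically associating domains (ASTADs)
    from haplotype-resolved Hi-C contact matrices. Provides Knight-Ruiz matrix
    balancing, observed/expected distance normalization, joint loess
    normalization of the two allelic matrices, median-filter denoised
    subtraction matrices, TAD scoring against a chromosome-wide background
    Z-score, conserved-ASTAD detection by reciprocal overlap, randomization
    enrichment tests for genomic features at domains and boundaries, phased
    variant concordance metrics, virtual-4C viewpoint traces, and a synthetic
    diploid Hi-C generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
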