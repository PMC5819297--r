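Package: chromoscan
Title: Repeat Composition, Coverage Profiling and Tandem-Array Screening for
    Heterochromatic Short-Read Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the in-silico dissection of pericentromeric
    heterochromatin (chromocenter) DNA from short sequencing reads. Implements
    sliding-window read cleaning, classification of reads against a repeat
    consensus library by best local alignment (affine-gap Smith-Waterman with
    a lossless k-mer seed prefilter), hierarchical repeat-composition tables,
    per-nucleotide coverage profiles along transposable-element consensuses
    with enrichment-segment calling, detection of large tandem-repeat arrays
    in contigs, and a co-occurrence screen for contigs carrying both tandem
    repeat monomers and endogenous retrovirus fragments. Ships a seeded
    synthetic-data generator (reads, libraries, contigs) with ground-truth
    tables so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    IRanges
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
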