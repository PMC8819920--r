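Package: scLongReads
Title: Demultiplexing, UMI Merging, Isoform and Immune-Receptor Analysis
    for Single-Cell Long-Read Consensus Data
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Processes full-length cDNA consensus reads from droplet-based
    single-cell experiments sequenced with long-read consensus protocols.
    Builds a cell-barcode whitelist by counting, assigns reads to cells
    with explicit Levenshtein-distance criteria, merges reads derived from
    the same circularization event (splint UMI) and the same RNA molecule
    (10X UMI) in two sequential steps, merges transcript isoform models
    called per cell under splice-site and end-site tolerance rules, tests
    genes for differential isoform usage between cell types with a
    chi-square contingency test, and assembles, annotates, and pairs
    adaptive immune receptor (IG and TCR) transcripts per cell. A
    synthetic-read simulator with ground truth supports validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
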