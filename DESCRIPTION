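Package: scisodemux
Title: Demultiplexing Concatenated Single-Cell Long-Read Isoform Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for processing concatenated multi-cDNA long reads from
    high-throughput single-cell isoform sequencing libraries. Locates 5' and 3'
    cDNA primers on high-accuracy long reads with an internal seed-and-extend
    local aligner, splits concatemers at primer and ligation-junction
    boundaries, classifies each cDNA unit as full-length non-chimeric (FLNC),
    non-full-length or artifact, orients transcripts, extracts and corrects
    16 bp cell barcodes against a whitelist using a quality-weighted posterior,
    filters and deduplicates 12 bp unique molecular identifiers by Hamming
    distance, and builds sparse gene-by-cell and isoform-by-cell UMI count
    matrices. Includes a concatemer library simulator with full ground truth
    and a confusion-matrix evaluator so the whole pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    S4Vectors,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
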