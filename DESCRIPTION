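Package: mobiscan
Title: Discovery, Genotyping and Population Analysis of Transposable
    Element Insertion Polymorphisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for transposable element (TE) insertion
    polymorphism analysis from short-read resequencing data. Builds a
    non-redundant TE end-sequence library, identifies TE-junction reads and
    clusters breakpoints into a population locus set, performs per-accession
    presence/absence genotyping from breakpoint-spanning reads, applies a
    four-rule locus filter cascade, and computes population-frequency
    spectra, morphotype-differential fixation, gene-proximity annotation,
    subgenome statistics, and binary-marker population genetics
    (neighbor-joining trees, PCA, Weir & Cockerham 1984 FST). Includes a
    deterministic mobilome simulator with target-site duplications that
    emits reads, truth tables and annotations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    rtracklayer,
    ape,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
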