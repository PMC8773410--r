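Package: nitromir
Title: Small RNA Tag Processing, miRNA Discovery and Differential
    Expression Under Nitrogen Deprivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-style re-implementation of a small RNA-seq analysis
    pipeline for Chlamydomonas reinhardtii grown with and without a nitrogen
    source: adaptor trimming and tag collapsing, classification against
    noncoding-RNA and mature miRNA references, novel miRNA hairpin discovery
    with an internal nearest-neighbour RNA folding engine, exact Poisson
    (Audic-Claverie) two-library differential expression, rule-based miRNA
    target prediction with G-U wobble scoring, and KOG functional
    summarization. Includes a synthetic-data generator that plants genomic
    hairpins, fold changes and target sites with known ground truth so the
    whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    IRanges,
    S4Vectors,
    generics,
    GenomicRanges,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
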