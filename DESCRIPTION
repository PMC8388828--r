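Package: vireco
Title: Virus-Host Prediction and Viral Community Ecology for Aquatic Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for linking environmental viruses to their
    prokaryotic hosts and comparing virus and host communities across sites
    and seasons. Implements CRISPR-spacer, shared-tRNA and sequence-homology
    evidence searches with a weighted consensus host score; CRISPR array
    detection and spacer extraction; dereplication and Dice-distance
    phylogenomic lineage assignment for phage genomes; read-mapping presence
    rules, abundance normalization, shared-membership partitions of
    communities, Bray-Curtis dissimilarity and Mantel correlation. Ships a
    synthetic-data generator that plants ground-truth CRISPR arrays,
    protospacers, tRNAs, homologous segments, reads and count matrices so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    Biostrings,
    IRanges,
    ape,
    phangorn,
    vegan,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
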