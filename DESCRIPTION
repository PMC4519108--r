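Package: ssrforge
Title: Cross-Genotype Microsatellite Marker Discovery from Draft Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An in-silico pipeline for discovering polymorphic simple
    sequence repeat (SSR, microsatellite) markers between two related
    genome or transcript assemblies. Enriches contig sets by the N50
    length rule, scans for perfect tandem repeats (motif period 2-7,
    minimum tract length 20 bp), designs flanking primer pairs and screens
    them for uniqueness, matches SSR-bearing contigs reciprocally between
    genotypes and predicts repeat-length polymorphism, removes organellar
    and repetitive sequences by homology-keyword blacklists, categorizes
    repeats relative to protein-homology regions, hard-filters VCFs by
    depth and mapping quality with substitution-spectrum counting, and
    tabulates motif-class and polymorphism-rate summaries. Includes a
    seeded synthetic two-genotype generator with planted repeat truth so
    every stage is testable without external data.
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
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
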