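Package: matdosage
Title: Maternal Transcript Dosage Analysis Across Oocyte Maturation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying post-transcriptional control of maternal
    transcript dosage across mouse oocyte maturation (GV to MII) and in
    maternal knockouts of m6A reader proteins. Implements empirical-Bayes
    moderated t-statistics with Benjamini-Hochberg adjustment and
    fold-change/p-value dosage calling, maturation-class gating and
    cross-tabulation against knockout calls, positional RNA-motif occurrence
    profiling around start and stop codons with hypergeometric set
    enrichment, and scale-regions metagene profiling of m6A peak intervals
    over gene bodies, together with a fully seeded synthetic
    maternal-transcriptome generator carrying ground-truth labels so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
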