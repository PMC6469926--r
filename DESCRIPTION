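Package: mitolineage
Title: Single-Cell Lineage Tracing from Mitochondrial DNA Heteroplasmies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls heteroplasmic mitochondrial DNA variants from stranded
    per-position allele-count tables (as produced from ATAC-seq alignments),
    applies a blacklist / strand-balance / allele-frequency filter cascade,
    re-genotypes accepted variants in single cells, models per-site and
    combined detection rates as a function of sequencing depth, and groups
    co-detected variants into clone-defining sets to assign cells to clonal
    lineages with doublet flagging. Ships a synthetic-data simulator with
    known clonal ground truth so every stage is testable at desk scale, and
    a command-line pipeline tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    Biostrings,
    GenomicRanges,
    IRanges,
    mclust,
    Rsamtools,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
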