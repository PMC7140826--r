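Package: haplodiv
Title: Haplotype Diversity, Classification and Network Analysis for
    mtDNA Control-Region Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for population-genetic analysis of aligned
    mitochondrial control-region sequences: collapsing samples into
    haplotypes and matching them against a named catalog, assigning
    haplogroups and sub-haplogroups from configurable diagnostic-mutation
    rules, classifying universal-type (UT) and UT-derived (UTd) haplotypes,
    computing per-region diversity statistics (haplotype and nucleotide
    diversity with standard deviations, rarefied haplotype counts by
    resampling without replacement with a closed-form hypergeometric
    check), and building minimum spanning networks over substitution
    distances including all alternative minimum-length connections. A
    synthetic-population generator with exact ground truth supports
    testing and documentation without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
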