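Package: snofam
Title: Expression Profiling of snoRNA Families Across Human Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Characterizes multi-copy small nucleolar RNA (snoRNA) families
    from a family-annotated snoRNA table and a tissue-replicate TPM matrix:
    expression status calling, family composition, pairwise sequence identity
    via longest-common-subsequence alignment scoring, per-base conservation
    and SNP density summaries, host-transcript assignment with distance to the
    downstream exon, family-versus-member abundance variability
    (coefficient-of-variation statistics), detection of tissue switches in the
    most abundant family member, and genomic-context classification. Ships a
    synthetic cohort generator with planted ground truth so the full pipeline
    runs and validates without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    Rcpp,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
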