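Package: poolquant
Title: Quantification of Highly Similar Genomes Pooled in One Sequencing
    Sample
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Reference-based quantification of the relative abundance of
    genomes - including highly similar variants such as phage cocktail
    members - pooled together in a single paired-end short-read sequencing
    sample.  Read pairs that align perfectly and uniquely to one reference
    seed per-genome coverages; pairs that tie across several references are
    then allocated proportionally to those coverages, with a dedicated
    pre-pass for tied references lacking any unique support.  Ships an
    exact ungapped paired-end aligner for self-contained use, a SAM/BAM
    ingestion path for external mappers, a mixture simulator with
    controlled pairwise identity and substitution errors, and evaluation
    utilities (quantification error, false negatives and positives,
    complexity-stratified summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    Rsamtools,
    stats,
    tibble,
    tidyr,
    utils,
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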