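Package: cernet
Title: Long Non-Coding RNA Identification and Competing Endogenous RNA
    Network Screening for Expression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-quantification analysis toolkit for long non-coding RNA
    (lncRNA) studies: structural and consensus coding-potential filters for
    lncRNA identification, a self-contained conditional negative-binomial
    exact test for differential expression, cis (genomic window) and trans
    (expression correlation) target-gene assignment, hypergeometric
    term-enrichment, and construction of competing endogenous RNA
    (lncRNA-miRNA-mRNA) networks via Spearman/Pearson correlation and
    shared-miRNA hypergeometric filters. Includes a negative-binomial
    synthetic-data generator with planted ceRNA triads so every stage is
    testable end to end, and a deterministic pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
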