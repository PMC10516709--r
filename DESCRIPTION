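Package: starraudit
Title: Auditing STARR-Seq Peak Sets Against Predicted Cis-Regulatory Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Audits STARR-seq enhancer peak sets against a genome-wide
    predicted catalog of cis-regulatory modules (CRMs) and non-CRMs.
    Partitions every analyzable base into six mutually exclusive categories
    by crossing CRM status and predicted functional state with STARR peak
    overlap, calls CRM functional states from four epigenetic-mark signals
    with a logistic-regression predictor, and characterizes the categories
    with TFBS-density complexity scores, matched-random-background
    enrichment of chromatin states and transposable elements, conservation
    and expression comparisons, and signal profile matrices. Ships a seeded
    synthetic-genome generator so the full pipeline is testable end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
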