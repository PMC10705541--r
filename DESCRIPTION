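Package: promint
Title: Promoter-Centric Integration of Transcription Factor Binding and
    Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative regulatory genomics for transcription factors that
    act at promoters. Provides tidy, pipe-friendly tools for peak-set
    concordance (base-pair Jaccard, reciprocal overlap counts), the relative
    distance statistic of peaks to gene elements, peak classification against
    gene models, position weight matrix scanning with exact dynamic
    programming p-values, anchor-centered coverage meta-profiles and
    heatmap matrices, CAGE tag clustering with dominant TSS calling and core
    promoter element architecture, and binding-by-differential-expression
    contingency statistics with Fisher odds ratios and Bonferroni-corrected
    term enrichment.  A seeded synthetic data generator produces
    self-contained genome/annotation/peak/coverage/CAGE/expression bundles
    with planted signal so every stage can be exercised and calibrated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
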