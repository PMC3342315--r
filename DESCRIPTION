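Package: tfdirect
Title: Direct Transcription-Factor Target Identification from Promoter
    Binding, Knockdown Expression and Tumor Co-Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for identifying the direct target
    genes of a transcription factor. Scored ChIP-chip promoter peaks are
    screened by peak-level FDR and purged of peaks shared with a
    non-specific IgG control, surviving peaks are assigned to promoter
    windows and summarized as TSS-relative binding histograms, and
    fixed-width windows around peak centers are scanned with a position
    weight matrix library to rank motif enrichment against shuffled
    background sequence. A single-array-per-condition differential
    expression test uses the log fold change as the statistic with an
    empirical normal null estimated from control-versus-control ratios and
    Benjamini-Hochberg adjustment. Binding and expression gene sets are
    synthesized by hypergeometric co-occurrence statistics, and candidate
    targets are scored for co-upregulation with the factor across a tumor
    cohort of expression Z-scores (odds ratios with one-sided Fisher
    tests, and a chi-square comparison of the target set against the
    genome-wide background). A fully seeded synthetic-data generator
    emulates every input with known ground truth so each stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
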