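Package: svtrr
Title: Benchmarking Structural Variant Callsets in and outside Tandem Repeat Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for evaluating structural variant (SV) callsets against a
    truth set, with emphasis on tandem repeat regions (TRRs). Reads and filters
    SV calls from VCF (including the PBHoney Spots dialect), builds interval sets
    from UCSC RepeatMasker tables and BED files, matches insertions by breakpoint
    distance and deletions by reciprocal overlap, and reports precision, recall
    and F1 stratified by SV type, TRR status and size bin. Also computes
    multi-caller concordance summaries, concurrent-detection histograms against a
    benchmark, and trio "de novo" rates, and ships a synthetic-data generator
    that plants callsets with fully known ground truth for exact parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
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
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
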