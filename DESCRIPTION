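Package: exonarh
Title: Entropy-Based Alternative Splicing and Differential Expression
    Analysis for Two-Condition Exon Arrays
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for two-condition exon-array experiments:
    GC-stratified background baseline correction, quantile normalization,
    probe-to-exon/gene median summarization, present/absent calls against
    GC-matched background control probes, gene-level differential expression
    by fold-change and exact rank-sum testing with small replicate groups,
    and entropy-based alternative-splicing detection (ARH) with per-exon
    splicing probabilities and resampling p-values. Includes a probe-level
    simulator with known differential-expression and cassette-exon splicing
    ground truth, QTL-interval localization of hits, and an end-to-end
    deterministic driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    limma,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
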