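Package: epicoop
Title: Cooperative Epigenetic Derepression Analysis for Combined
    EZH2/HDAC Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Discovery pipeline for Polycomb (PRC2) target genes that are
    cooperatively derepressed by combined EZH2 and HDAC inhibition.
    Implements H3K27me3 peak-loss calling within transcription start site
    windows, triple-contrast selection of combination-specific induced
    genes, candidate intersection with provenance tracking, single-sample
    and classic gene set enrichment scoring, tumor-cohort z-scoring,
    decile stratification and Kaplan-Meier/log-rank survival analysis,
    and highest-single-agent (HSA) drug-synergy scoring.  A synthetic
    data generator with planted ground truth emulates the full study
    design so every stage is testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
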