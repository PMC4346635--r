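Package: chicflow
Title: Capture Hi-C Interaction Calling and Domain Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for capture Hi-C (cHi-C)
    experiments: in-silico restriction digestion, assembly and filtering of
    Hi-C ditags, binned contact matrices partitioned by capture-enrichment
    class, capture-aware iterative bias correction, distance normalization
    against a smoothed power-law template, significance calling with a
    zero-inflated Weibull null model and FDR control, directionality-index
    based topological domain calling, and the downstream enrichment and
    overlap statistics (capture enrichment factor, association-signal
    overlap, Monte Carlo regulatory-element overlap, transcription-factor
    sharing). A ditag-level simulator with full ground truth supports
    closed-loop validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
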