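Package: ctscreen
Title: Plate-Based qRT-PCR Screening Analysis with DDCt Quantification and
    Dose-Response Confirmation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput transcriptional screens
    read out by quantitative RT-PCR on 384-well plates. Implements Livak
    2^-ddCt relative quantification against in-plate DMSO vehicle controls,
    plate-wise Z-score hit calling with a triple criterion (fold change,
    ddCt Z-score, calibrator-gene Z-score gate), duplicate-replicate
    reconciliation across a screening campaign, four-parameter logistic
    dose-response fitting for EC50 estimation, minimal-effective-concentration
    summaries, and landmark expression profiling (quantile normalization,
    log2 fold change versus vehicle, signal-to-noise marker selection).
    Includes ground-truth simulators for Ct plates, screening campaigns,
    dose-response assays and two-group expression profiles, with
    truth-based recall and false-discovery evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    minpack.lm,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
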