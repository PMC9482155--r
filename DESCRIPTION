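Package: urometh
Title: Urine DNA Methylation Biomarker Panels for Bladder Cancer Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building and evaluating urine DNA methylation biomarker
    panels for bladder cancer triage. Covers sliding-window discovery of
    differentially methylated regions from per-CpG bisulfite methylation
    calls, per-marker ROC threshold calibration under a specificity
    constraint, three-state panel scoring (negative / inconclusive /
    positive), and diagnostic-accuracy evaluation with exact confidence
    intervals and prevalence-based predictive values. Includes seeded
    synthetic-data generators emulating cell-line RRBS profiles with planted
    differentially methylated regions and urine cohorts with a latent
    tumor-shedding factor, so the whole pipeline is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
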