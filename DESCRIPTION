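Package: renomark
Title: Kidney-Specific Cell-Free DNA Methylation Markers: Discovery,
    Digital PCR Quantification and Diagnostic Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for discovering kidney- and compartment-specific DNA
    methylation marker blocks from a multi-tissue whole-genome bisulfite
    methylation atlas, for quantifying those markers in cell-free DNA by
    multiplex digital PCR with an albumin internal control (Poisson
    partition statistics, confidence intervals, control validation,
    replicate reproducibility, and limit-of-detection modeling under
    bisulfite conversion loss), and for diagnostic modeling of kidney
    allograft injury (univariate and multivariate logistic regression,
    epigenetic signature construction, ROC/AUC model comparison).
    Includes seeded synthetic-data generators for atlases, digital PCR
    plates and patient cohorts with machine-readable truth tables for
    recovery testing, and a pipeline runner chaining all stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
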