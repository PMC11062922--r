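Package: kinobeadr
Title: Kinobeads Competition-Binding Analysis for Kinase Inhibitor Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for Kinobeads competition-binding
    chemoproteomics. Reads MaxQuant-style protein-group tables with a plate
    layout, normalizes pulldown intensities to DMSO vehicle controls,
    estimates apparent dissociation constants (Kd app) from two-dose or full
    dose-response profiles with per-protein bead-depletion correction, calls
    compound targets with a rule-annotated random-forest classifier,
    scores inhibitor selectivity (CATDS), nominates chemical-probe
    candidates, computes replicate-based assay performance metrics, and
    analyzes TMT phosphoproteomics regulation with an S0-moderated test at
    controlled FDR. Ships a ground-truthed synthetic-data generator that
    emulates the plate design and noise structure of the assay so that every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
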