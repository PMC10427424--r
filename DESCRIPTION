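Package: clonalrevival
Title: Clonotype Dynamics, Immune Signatures and Clinical Statistics for
    Neoadjuvant Immunotherapy Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for translational analysis of neoadjuvant checkpoint
    blockade trials in solid tumors: TCR-beta repertoire quality control,
    richness and clonality; tracking of intratumoral T cell clonotypes
    (ITCs) across paired tumors and longitudinal blood with Fisher-exact
    expansion/contraction calls; single-sample GSEA hallmark scoring,
    mean-expression immune signatures and an elastic-net IFN/EMT score;
    tumor-microenvironment subtype clustering; neoantigen binding-filter
    cascades and TCR-neoantigen linkage; and trial-level clinical
    statistics (pathological response classes, weighted Kaplan-Meier and
    log-rank, inverse-probability-of-treatment weighting with balance
    diagnostics, and Simon two-stage operating characteristics). A
    synthetic cohort generator with planted ground truth makes every
    stage testable without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    nnet,
    stats,
    utils,
    withr
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
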