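Package: pmsig
Title: Proteomic Signature Discovery for Peritoneal-Metastasis Risk in Gastric Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for discovering and validating
    a proteomic risk signature of gastric-cancer peritoneal metastasis (PM) from
    TMT-style quantitative proteomes. Implements fraction-of-total (FOT)
    normalization and unique-peptide filtering, SAM-style permutation
    differential-expression testing intersected with a per-pair t-distribution
    fold-change test, signal-to-noise (SNR) ranked phenotype-module selection
    with external transcriptome concordance filtering, cross-validated-AUC
    combinatorial panel selection with top-combination frequency ranking, a
    weighted PM risk score with quartile stratification, and Kaplan-Meier /
    log-rank / Cox survival validation. Ships a seeded synthetic cohort
    generator emulating a paired tumour/normal design with planted effects and
    survival outcomes, so every stage is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
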