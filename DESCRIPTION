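Package: immunoscape
Title: Immune Infiltration Scoring, Quadrant Stratification, and
    Pathway-Guided Candidate Gene Discovery for Tumor Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for bulk tumor transcriptomes
    centered on B-cell infiltration and PD-L1 (CD274) expression. Computes
    per-sample single-sample GSEA (ssGSEA) immune infiltration scores from
    signature gene sets, stratifies tumors into four quadrant groups by the
    median B-cell score and median PD-L1 expression, runs clinical
    statistics (paired signed-rank, Kruskal-Wallis with Dunn/Nemenyi
    post-hoc, Kaplan-Meier/log-rank, Cox proportional hazards), identifies
    the most variant genes by a one-way ANOVA-like F-test with
    Benjamini-Hochberg FDR, clusters patients by Ward linkage with
    silhouette model selection, performs two-group GSEA with
    signal-to-noise ranking and phenotype-permutation NES/FDR, selects
    differential pathways by the NES difference between contrasts,
    nominates candidate genes by a sequential fold-change filter over core
    enrichment genes, and tests drug-target overlap by a permutation null
    with a hypergeometric cross-check. Ships a synthetic cohort generator
    with known ground truth so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
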