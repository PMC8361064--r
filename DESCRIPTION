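Package: methcna
Title: Genome-Wide Methylation Density and Copy-Number Aberration
    Profiling of Plasma Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Liquid-biopsy methylome and copy-number analysis for
    low-pass bisulfite sequencing of plasma cell-free DNA. Computes
    per-megabase-bin methylation density, calls hypomethylated bins
    against a healthy-donor baseline (mean minus 3 SD), GC-corrects and
    median-normalizes bin read counts to call copy-number-aberrant bins
    by z-score, tests a targeted panel of regulatory regions for
    differential methylation (Wilcoxon rank-sum with Benjamini-Hochberg
    correction and a log2 fold-change cutoff), collapses UMI read
    families to consensus fragments for variant-allele-frequency
    estimation, and provides the cohort-level statistics (Pearson
    correlations with Fisher-z intervals, Mann-Whitney and
    Kruskal-Wallis tests, cohort summary tables) used to contrast
    EGFR-dependent and EGFR-independent TKI-resistance groups. A
    synthetic cohort generator emulates the healthy reference and
    patient groups so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
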