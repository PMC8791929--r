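Package: tp53hits
Title: Clonal and Sub-Clonal TP53 Lesion Calling, Double-Hit Classification
    and Prognostic Cutoff Derivation in Multiple Myeloma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for assessing TP53 allelic status in
    newly diagnosed and relapsed multiple myeloma. Converts purity-diluted
    SNP-array log2 ratios into absolute TP53 copy number and a deletion
    cancer cell fraction (CCF); merges three somatic variant callers under a
    2-of-3 consensus with tool, laboratory depth/VAF and pathogenicity
    filters; classifies patients as wild-type, single-hit or double-hit;
    derives the prognostic deletion-call CCF cutoff by a time-dependent
    (cumulative/dynamic, IPCW) ROC scan under right censoring; quantifies
    the survival impact of TP53 status with Kaplan-Meier and Cox
    proportional-hazards models; and tracks longitudinal evolution between
    diagnosis and relapse. A seeded synthetic-cohort generator with full
    ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    withr,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
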