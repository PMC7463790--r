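Package: salivaSF
Title: Splicing-Factor Transcript Panels in Saliva Cell-Free RNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for a saliva cell-free RNA splicing-factor
    biomarker panel: comparative-Ct quantification of qPCR targets against a
    normalizer gene, triplicate aggregation, a composite summed
    relative-expression score, per-target coefficient-of-variation
    reproducibility analysis, within- versus between-subject variance
    comparison, healthy-versus-patient cohort comparison with age
    stratification, random-subgroup permutation tests for treatment effects,
    RNA-seq count-table biotype and presence filtering, and clinical
    metadata summarization. Ships a hierarchical synthetic-data generator
    (subject random effects, day-level repeats, technical replicates) so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    jsonlite,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
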