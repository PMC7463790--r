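#!/usr/bin/env Rscript
# Reproducibility: per-target CV across ten days of one woman, and the
# permutation variance-ratio test of between-women vs within-woman spread.
suppressMessages(library(salivaSF))

repro <- readr::read_csv("results/repro_profiles.csv",
                         show_col_types = FALSE)
divers <- readr::read_csv("results/diversity_profiles.csv",
                          show_col_types = FALSE)

cv <- cv_report(repro)
readr::write_csv(cv, "results/cv_report.csv")
cat("median per-target CV across days:",
    sprintf("%.2f", median(cv$cv[cv$target != "composite_score"])), "\n")

vc <- compare_within_between(repro, divers, B = 10000, seed = 99L)
readr::write_csv(vc, "results/variance_comparison.csv")
comp <- vc[vc$endpoint == "composite_score", ]
cat(sprintf(
  "composite: between/within variance ratio %.2f (permutation p = %.4f)\n",
  comp$statistic, comp$p_value))
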