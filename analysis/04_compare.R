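#!/usr/bin/env Rscript
# Healthy vs patient comparison: per-target and composite permutation tests,
# then the same composite comparison inside young/old age strata.
suppressMessages(library(salivaSF))

prof <- readr::read_csv("results/cohort_profiles.csv",
                        show_col_types = FALSE)

res <- per_target_summary(prof, B = 10000, seed = 7L)
readr::write_csv(res, "results/group_comparison.csv")
comp <- res[res$endpoint == "composite_score", ]
cat(sprintf("composite score: healthy %.3f vs patient %.3f, p = %.4f\n",
            comp$mean_healthy, comp$mean_patient, comp$p_value))
sig <- res$endpoint[res$endpoint != "composite_score" & res$p_value < 0.05]
cat("targets at p < 0.05:", paste(sig, collapse = ", "), "\n")

strata <- stratify_by_age(prof)
cat("age cut (pooled median):", attr(strata, "age_cut"), "years\n")
strat_res <- dplyr::bind_rows(lapply(c("young", "old"), function(nm) {
  r <- compare_groups(strata[[nm]], "composite_score", B = 10000,
                      seed = 8L)
  dplyr::bind_cols(tibble::tibble(stratum = nm), r)
}))
readr::write_csv(strat_res, "results/age_strata_comparison.csv")
print(strat_res[, c("stratum", "n_healthy", "n_patient", "p_value")])
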