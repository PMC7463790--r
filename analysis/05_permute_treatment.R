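#!/usr/bin/env Rscript
# Treatment sub-groups: each canonical treatment label's patients against
# the remaining patients, by random-subgroup permutation (B = 1000).
suppressMessages(library(salivaSF))

prof <- readr::read_csv("results/cohort_profiles.csv",
                        show_col_types = FALSE)
meta <- parse_metadata("results/data/metadata.csv")

scan <- scan_treatment_effects(prof, meta, B = 1000, seed = 17L)
readr::write_csv(scan, "results/treatment_permutation.csv")
print(scan[, c("label", "n_subgroup", "observed_statistic", "p_value",
               "p_holm")])
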