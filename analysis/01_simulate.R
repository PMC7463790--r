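#!/usr/bin/env Rscript
# Generate the synthetic study bundle every later stage consumes:
#  - a case-control Ct dataset (36 healthy vs 31 ER+ patients, one day each)
#  - a reproducibility design (one woman, ten days) and a diversity design
#    (ten women, one day each)
#  - a pooled cell-free count table with a long-tailed abundance law
#  - the clinical characteristics table, linked to the simulated patients
suppressMessages(library(salivaSF))
seed <- 20260926L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

cohort_ct <- simulate_ct_dataset(ct_sim_config(), seed = seed)
readr::write_csv(cohort_ct, "results/data/cohort_ct.csv")

repro_ct <- simulate_ct_dataset(
  ct_sim_config(n_healthy = 1, n_patients = 0, n_repeat_days = 10),
  seed = seed + 1L)
readr::write_csv(repro_ct, "results/data/repro_ct.csv")

diversity_ct <- simulate_ct_dataset(
  ct_sim_config(n_healthy = 10, n_patients = 0), seed = seed + 2L)
readr::write_csv(diversity_ct, "results/data/diversity_ct.csv")

counts <- simulate_count_table(count_sim_config(), seed = seed + 3L)
readr::write_tsv(counts, "results/data/pool_counts.tsv")

meta <- parse_metadata(table1_path())
meta$patient_id <- unique(cohort_ct$subject_id[cohort_ct$group == "patient"])
write_metadata(meta, "results/data/metadata.csv")

cat("cohort wells:", nrow(cohort_ct),
    "| repro wells:", nrow(repro_ct),
    "| genes:", nrow(counts), "\n")
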