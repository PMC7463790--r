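#!/usr/bin/env Rscript
# Cohort characteristics from the clinical table: ages, metastatic burden,
# treatment sub-group sizes.
suppressMessages(library(salivaSF))

meta <- parse_metadata(table1_path())
s <- summarize_cohort(meta)
jsonlite::write_json(s, "results/cohort_summary.json", auto_unbox = TRUE,
                     digits = NA)
cat(sprintf("n = %d patients; age at collection %.0f +/- %.0f years\n",
            s$n, s$age_mean, s$age_sd))
cat(sprintf("metastatic: %.1f%%\n", s$pct_metastatic))
print(s$treatment_counts)
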