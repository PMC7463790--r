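#!/usr/bin/env Rscript
# Comparative-Ct quantification: triplicate aggregation, PPIA normalization,
# per-target relative expression and the composite summed score.
suppressMessages(library(salivaSF))

for (design in c("cohort", "repro", "diversity")) {
  ct <- readr::read_csv(sprintf("results/data/%s_ct.csv", design),
                        show_col_types = FALSE)
  prof <- quantify_profiles(ct)
  readr::write_csv(prof, sprintf("results/%s_profiles.csv", design))
  cat(design, ": ", nrow(prof), " samples, composite score ",
      sprintf("%.3f", mean(prof$composite_score)), " +/- ",
      sprintf("%.3f", sd(prof$composite_score)), "\n", sep = "")
}
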