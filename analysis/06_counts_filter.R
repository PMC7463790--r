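#!/usr/bin/env Rscript
# RNA-seq post-quantification stages: biotype exclusion, low-count filtering
# (row sum >= 3), presence calling at 49 reads, and the abundance histogram.
suppressMessages(library(salivaSF))

counts <- read_count_table("results/data/pool_counts.tsv")
no_bt <- exclude_biotypes(counts)
filtered <- filter_low_counts(no_bt, min_total = 3)
readr::write_tsv(filtered, "results/counts_filtered.tsv")

present <- call_present(filtered, threshold = 49)
writeLines(present, "results/present_genes.txt")

hist <- abundance_histogram(filtered,
                            bin_edges = c(1, 3, 10, 49, 100, 500, 1000))
readr::write_csv(hist, "results/abundance_histogram.csv")

cat("genes:", nrow(counts),
    "| after biotype exclusion:", nrow(no_bt),
    "| after low-count filter:", nrow(filtered),
    "| present at >= 49 reads:", length(present), "\n")
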