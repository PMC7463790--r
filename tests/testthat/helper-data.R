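# Small builders shared across test files.

# Well-level Ct table for hand-specified delta-Ct values: one sample,
# triplicates with zero spread, normalizer at `norm_ct`.
make_ct_table <- function(dct_by_target, norm_ct = 24,
                          sample_id = "S1", group = "healthy", age = 40) {
  tg <- names(dct_by_target)
  tibble::tibble(
    sample_id = sample_id, subject_id = sample_id, group = group,
    age = age, collection_day = 1L,
    target = rep(c(tg, SF_NORMALIZER), each = 3),
    replicate = rep(1:3, length(tg) + 1),
    ct = rep(c(norm_ct + dct_by_target, norm_ct), each = 3))
}

# Count table with explicit per-gene counts and biotypes.
make_count_table <- function(counts, biotype = "protein_coding") {
  n <- length(counts)
  tibble::tibble(
    gene_id = sprintf("G%04d", seq_len(n)),
    symbol = sprintf("Sym%d", seq_len(n)),
    biotype = rep_len(biotype, n),
    pool = as.integer(counts))
}

# Independent brute-force oracle: exact two-sided permutation p for the
# absolute difference of group means, by full enumeration over combn.
enumerate_mean_perm_p <- function(x, y) {
  pool <- c(x, y)
  nx <- length(x)
  obs <- abs(mean(x) - mean(y))
  cols <- utils::combn(length(pool), nx)
  hits <- 0
  for (j in seq_len(ncol(cols))) {
    a <- pool[cols[, j]]
    b <- pool[-cols[, j]]
    if (abs(mean(a) - mean(b)) >= obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(cols)
}

# Independent brute-force oracle for the subgroup permutation: exact tail
# proportion of |mean(subgroup) - mean(remainder)| over all subgroups of
# size k.
enumerate_subgroup_p <- function(scores, k, obs) {
  cols <- utils::combn(length(scores), k)
  hits <- 0
  for (j in seq_len(ncol(cols))) {
    s <- scores[cols[, j]]
    r <- scores[-cols[, j]]
    if (abs(mean(s) - mean(r)) >= obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(cols)
}
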