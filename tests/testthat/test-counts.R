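test_that("biotype exclusion drops listed classes only", {
  tbl <- make_count_table(c(10, 20), biotype = c("snoRNA",
                                                 "protein_coding"))
  out <- exclude_biotypes(tbl)
  expect_equal(out$biotype, "protein_coding")
  expect_equal(attr(out, "n_removed"), 1)
  # empty excluded set is the identity
  expect_equal(nrow(exclude_biotypes(tbl, excluded = character(0))), 2)
  # missing biotype is kept with a warning
  tbl2 <- make_count_table(c(5, 5), biotype = c(NA, "rRNA"))
  expect_warning(out2 <- exclude_biotypes(tbl2), "lack a biotype")
  expect_equal(out2$gene_id, tbl2$gene_id[1])
  # constructed 20% excluded fraction comes back exactly
  n <- 200
  bt <- rep("protein_coding", n)
  bt[seq_len(n / 5)] <- sample(EXCLUDED_BIOTYPES, n / 5, replace = TRUE)
  tbl3 <- make_count_table(rep(1, n), biotype = bt)
  out3 <- exclude_biotypes(tbl3)
  expect_equal(attr(out3, "n_removed"), n / 5)
  expect_equal(nrow(out3), n - n / 5)
})

test_that("low-count filter applies the row-sum boundary as documented", {
  two_col <- tibble::tibble(gene_id = c("a", "b"), biotype = "pc",
                            s1 = c(1L, 3L), s2 = c(1L, 0L))
  out <- filter_low_counts(two_col, min_total = 3)
  expect_equal(out$gene_id, "b")   # sum 2 removed, sum 3 (boundary) kept
  # constructed fixture: 37 genes with row-sum <= 2 out of 100
  counts <- c(rep(0:2, length.out = 37), rep(3:50, length.out = 63))
  tbl <- make_count_table(counts)
  kept <- filter_low_counts(tbl, min_total = 3)
  expect_equal(nrow(kept), 63)
  expect_equal(attr(kept, "n_removed"), 37)
  # idempotent
  expect_equal(nrow(filter_low_counts(kept, min_total = 3)), 63)
  # malformed tables are rejected
  expect_error(filter_low_counts(make_count_table(c(-1, 2))),
               "non-negative")
  bad <- make_count_table(c(1, 2)); bad$gene_id <- c("x", "x")
  expect_error(filter_low_counts(bad), "unique")
})

test_that("presence calling respects the 49-read boundary convention", {
  tbl <- make_count_table(c(48, 49, 50, 0))
  expect_setequal(call_present(tbl, threshold = 49),
                  tbl$gene_id[c(2, 3)])
  expect_setequal(call_present(tbl, threshold = 49, inclusive = FALSE),
                  tbl$gene_id[3])
  expect_setequal(call_present(tbl, threshold = 0), tbl$gene_id)
  # present-set size is non-increasing in the threshold
  withr::with_seed(8, big <- make_count_table(rpois(500, 30)))
  sizes <- vapply(c(0, 10, 30, 60, 200),
                  function(th) length(call_present(big, th)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  # a fixture built with exactly 1254 genes at or above threshold
  counts <- c(rep(49L, 1254), rep(48L, 746))
  expect_length(call_present(make_count_table(counts), 49), 1254)
})

test_that("abundance histogram conserves mass over half-open bins", {
  one <- make_count_table(5)
  h <- abundance_histogram(one, bin_edges = c(10, 100))
  expect_equal(sum(h$n_genes), 1)
  # known occupancies: [0,10) x3, [10,50) x2, [50,Inf) x1
  tbl <- make_count_table(c(0, 9, 3, 10, 49, 50))
  h2 <- abundance_histogram(tbl, bin_edges = c(10, 50))
  expect_equal(h2$n_genes, c(3L, 2L, 1L))
  # mass conserved for arbitrary tables and bins
  withr::with_seed(5, rnd <- make_count_table(rpois(300, 20)))
  h3 <- abundance_histogram(rnd, bin_edges = c(1, 5, 25, 125))
  expect_equal(sum(h3$n_genes), 300)
  expect_error(abundance_histogram(rnd, bin_edges = c(5, 1)),
               "increasing")
})

test_that("the documented filter chain is order-stable and idempotent", {
  withr::with_seed(12, {
    bt <- sample(c("protein_coding", "snoRNA", "rRNA"), 300, TRUE,
                 prob = c(0.7, 0.15, 0.15))
    tbl <- make_count_table(rpois(300, 4), biotype = bt)
  })
  once <- filter_low_counts(exclude_biotypes(tbl), 3)
  twice <- filter_low_counts(exclude_biotypes(once), 3)
  attr(once, "n_removed") <- NULL
  attr(twice, "n_removed") <- NULL
  expect_equal(as.data.frame(once), as.data.frame(twice))
  expect_equal(attr(exclude_biotypes(once), "n_removed"), 0)
  present <- call_present(once, 49)
  expect_true(all(present %in% once$gene_id))
})

test_that("count table reader accepts merged and bare HTSeq formats", {
  tbl <- make_count_table(c(7, 80), biotype = c("protein_coding", "rRNA"))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tbl, tmp)
  back <- read_count_table(tmp)
  expect_equal(as.data.frame(back), as.data.frame(tbl))
  # bare two-column file with HTSeq summary rows
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("G1\t12", "G2\t0", "__no_feature\t999"), tmp2)
  bare <- read_count_table(tmp2)
  expect_equal(bare$gene_id, c("G1", "G2"))
  expect_equal(bare$pool, c(12, 0))
})
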