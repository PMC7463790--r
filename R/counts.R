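#' Identify the count columns of a count table
#'
#' Everything except the annotation columns (`gene_id`, `symbol`,
#' `biotype`) is treated as a sample count column.
#' @param counts Count tibble.
#' @return Character vector of column names.
#' @export
count_columns <- function(counts) {
  setdiff(names(counts), c("gene_id", "symbol", "biotype"))
}

.check_count_table <- function(counts) {
  if (!"gene_id" %in% names(counts))
    stop("count table needs a gene_id column", call. = FALSE)
  if (anyDuplicated(counts$gene_id))
    stop("gene_ids must be unique", call. = FALSE)
  cc <- count_columns(counts)
  if (!length(cc)) stop("no sample count columns", call. = FALSE)
  for (cl in cc) {
    v <- counts[[cl]]
    if (!is.numeric(v) || any(v < 0, na.rm = TRUE) ||
        any(v != floor(v), na.rm = TRUE))
      stop("counts must be non-negative integers (column ", cl, ")",
           call. = FALSE)
  }
  cc
}

#' Remove genes of excluded biotypes
#'
#' Drops every row whose `biotype` is in the excluded set (immunoglobulin /
#' TCR segments, artifacts and short non-coding RNA classes by default).
#' Rows with a missing biotype are retained with a warning — exclusion is by
#' listed class only.
#'
#' @param counts Count tibble with a `biotype` column.
#' @param excluded Character set of biotypes (default [EXCLUDED_BIOTYPES]).
#' @return Filtered tibble; the number of rows removed is attached as
#'   attribute `n_removed`.
#' @export
exclude_biotypes <- function(counts, excluded = EXCLUDED_BIOTYPES) {
  .check_count_table(counts)
  if (!"biotype" %in% names(counts))
    stop("count table needs a biotype column", call. = FALSE)
  miss <- is.na(counts$biotype) | counts$biotype == ""
  if (any(miss))
    warning(sum(miss), " gene(s) lack a biotype annotation and were kept",
            call. = FALSE)
  drop <- !miss & counts$biotype %in% excluded
  out <- counts[!drop, ]
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Remove genes with too few reads overall
#'
#' Drops genes whose summed count across all samples is below `min_total`
#' (boundary: a row-sum equal to `min_total` is kept).
#'
#' @param counts Count tibble.
#' @param min_total Minimum total reads (default 3).
#' @return Filtered tibble with attribute `n_removed`.
#' @export
filter_low_counts <- function(counts, min_total = 3) {
  cc <- .check_count_table(counts)
  if (min_total < 0) stop("min_total must be >= 0", call. = FALSE)
  totals <- rowSums(as.matrix(counts[, cc, drop = FALSE]))
  out <- counts[totals >= min_total, ]
  attr(out, "n_removed") <- sum(totals < min_total)
  out
}

#' Call genes present in a pooled saliva sample
#'
#' Flags a gene present when its read count reaches the presence threshold
#' (default 49 reads; boundary convention: exactly 49 is present, set
#' `inclusive = FALSE` for a strict `>`). The table must have a single
#' count column or `sample` must name one.
#'
#' @param counts Count tibble.
#' @param threshold Reads needed for presence (default 49).
#' @param sample Count column to use; required when several exist.
#' @param inclusive Presence at `count >= threshold` (default) vs `>`.
#' @return Character vector of present `gene_id`s.
#' @export
call_present <- function(counts, threshold = 49, sample = NULL,
                         inclusive = TRUE) {
  cc <- .check_count_table(counts)
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  if (is.null(sample)) {
    if (length(cc) > 1)
      stop("several count columns; name one via `sample`", call. = FALSE)
    sample <- cc
  }
  if (!sample %in% cc) stop("no count column '", sample, "'", call. = FALSE)
  v <- counts[[sample]]
  keep <- if (inclusive) v >= threshold else v > threshold
  counts$gene_id[keep]
}

#' Gene-abundance histogram
#'
#' Number of genes per read-count bin, the view used to judge how deep a
#' pooled cell-free sample samples the transcriptome. `bin_edges` are cut
#' points: the bins are `[0, e1), [e1, e2), ..., [ek, Inf)`, so every gene
#' falls in exactly one bin and the histogram mass always equals the number
#' of genes.
#'
#' @param counts Count tibble.
#' @param bin_edges Strictly increasing non-negative cut points.
#' @param sample Count column to use; required when several exist.
#' @return Tibble: `bin_lo`, `bin_hi` (Inf for the last), `n_genes`.
#' @export
abundance_histogram <- function(counts, bin_edges, sample = NULL) {
  cc <- .check_count_table(counts)
  if (!nrow(counts)) stop("empty count table", call. = FALSE)
  if (length(bin_edges) < 1 || is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing", call. = FALSE)
  if (is.null(sample)) {
    if (length(cc) > 1)
      stop("several count columns; name one via `sample`", call. = FALSE)
    sample <- cc
  }
  v <- counts[[sample]]
  edges <- c(0, bin_edges[bin_edges > 0], Inf)
  idx <- findInterval(v, edges, left.open = FALSE)  # [lo, hi) bins
  tibble::tibble(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1],
    n_genes = as.integer(tabulate(idx, nbins = length(edges) - 1)))
}

#' Read an HTSeq-style count table from TSV
#'
#' Accepts either a merged matrix with `gene_id`/`symbol`/`biotype`
#' annotation columns followed by one column per sample, or a bare
#' two-column `gene_id<TAB>count` file (no header), in which case the count
#' column is named `pool`. HTSeq's trailing `__no_feature`-style summary
#' rows are dropped.
#'
#' @param path TSV file path.
#' @return Count tibble.
#' @export
read_count_table <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("gene_id", first, fixed = TRUE)) {
    out <- readr::read_tsv(path, show_col_types = FALSE,
                           progress = FALSE)
  } else {
    out <- readr::read_tsv(path, col_names = c("gene_id", "pool"),
                           show_col_types = FALSE, progress = FALSE)
  }
  out[!grepl("^__", out$gene_id), ]
}
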