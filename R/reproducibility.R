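#' Coefficient of variation of a relative-expression series
#'
#' CV = sample SD (n - 1 denominator) / mean; a scale-free reproducibility
#' measure, invariant under positive rescaling and zero iff all values are
#' equal. Undefined (NA, with `ok = FALSE`) when fewer than two values or a
#' non-positive mean. A conventional reproducibility flag at CV <= 0.25 is
#' reported but nothing hard-fails on it.
#'
#' @param values Numeric vector, e.g. one subject's relative expression of
#'   one target across collection days.
#' @param flag_threshold CV below which the series is flagged reproducible.
#' @return One-row tibble: `n`, `mean`, `sd`, `cv`, `reproducible`, `ok`.
#' @examples
#' cv_stat(c(1, 2, 3)) # cv = 0.5
#' @export
cv_stat <- function(values, flag_threshold = 0.25) {
  values <- values[!is.na(values)]
  n <- length(values)
  m <- if (n) mean(values) else NA_real_
  s <- if (n >= 2) stats::sd(values) else NA_real_
  ok <- n >= 2 && !is.na(m) && m > 0
  cv <- if (ok) s / m else NA_real_
  tibble::tibble(n = n, mean = m, sd = s, cv = cv,
                 reproducible = ok && cv <= flag_threshold, ok = ok)
}

#' Per-target CV report across repeat samples
#'
#' Computes [cv_stat()] for every panel target (and the composite score)
#' over the rows of a profile table — typically one subject measured on
#' several days (reproducibility design) or several subjects measured once
#' (diversity design). CVs are computed on the relative-expression scale.
#'
#' @param profiles Profile tibble from [quantify_profiles()].
#' @param targets Target columns to report (default [SF_PANEL]).
#' @param include_composite Also report the composite score row.
#' @return Tibble with one row per target: `target`, `n`, `mean`, `sd`,
#'   `cv`, `reproducible`, `ok`.
#' @export
cv_report <- function(profiles, targets = SF_PANEL,
                      include_composite = TRUE) {
  targets <- intersect(targets, names(profiles))
  if (!length(targets)) stop("no target columns found", call. = FALSE)
  cols <- c(targets,
            if (include_composite && "composite_score" %in% names(profiles))
              "composite_score")
  dplyr::bind_rows(lapply(cols, function(cl) {
    dplyr::bind_cols(tibble::tibble(target = cl), cv_stat(profiles[[cl]]))
  }))
}

#' Permutation variance-ratio test of between- vs within-subject spread
#'
#' Tests whether the variance across different subjects exceeds the
#' day-to-day variance within one subject. The statistic is the ratio
#' `var(between series) / var(within series)`; its null distribution is
#' built by pooling the two series and randomly re-splitting into groups of
#' the original sizes B times (one-sided: large ratios are evidence that
#' subjects differ more than days do). A permutation reference is used
#' rather than the F distribution because relative-expression values are not
#' assumed normal; set `method = "f"` for the parametric alternative.
#'
#' @param within_values Numeric series from one subject across days
#'   (length >= 2).
#' @param between_values Numeric series from different subjects, one sample
#'   each (length >= 2).
#' @param B Number of permutations.
#' @param seed Optional integer seed.
#' @param method `"permutation"` (default) or `"f"` (one-sided F-test).
#' @return One-row tibble: `within_variance`, `between_variance`,
#'   `statistic` (ratio), `p_value`, `method`, `B`.
#' @export
variance_ratio_test <- function(within_values, between_values, B = 1000,
                                seed = NULL,
                                method = c("permutation", "f")) {
  method <- match.arg(method)
  within_values <- within_values[!is.na(within_values)]
  between_values <- between_values[!is.na(between_values)]
  nw <- length(within_values); nb <- length(between_values)
  if (nw < 2 || nb < 2)
    stop("both series need at least two values", call. = FALSE)
  vw <- stats::var(within_values)
  vb <- stats::var(between_values)
  if (vw == 0 && vb == 0) {                     # degenerate: no spread at all
    return(tibble::tibble(within_variance = 0, between_variance = 0,
                          statistic = NA_real_, p_value = 1,
                          method = method, B = NA_integer_))
  }
  stat <- vb / vw
  if (method == "f") {
    p <- stats::pf(stat, nb - 1, nw - 1, lower.tail = FALSE)
    return(tibble::tibble(within_variance = vw, between_variance = vb,
                          statistic = stat, p_value = max(p, .Machine$double.xmin),
                          method = "f", B = NA_integer_))
  }
  if (!is.null(seed)) withr::local_seed(seed)
  pool <- c(within_values, between_values)
  n <- nw + nb
  perm <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, nb)
    stats::var(pool[idx]) / stats::var(pool[-idx])
  }, numeric(1))
  p <- (sum(perm >= stat) + 1) / (B + 1)
  tibble::tibble(within_variance = vw, between_variance = vb,
                 statistic = stat, p_value = p,
                 method = "permutation", B = as.integer(B))
}

#' Compare within- and between-subject variability per endpoint
#'
#' Table-level wrapper around [variance_ratio_test()]: takes a
#' reproducibility profile table (one subject, several days) and a diversity
#' profile table (several subjects, one day each) and runs the test on the
#' composite score and each panel target.
#'
#' @param repro_profiles,diversity_profiles Profile tibbles from
#'   [quantify_profiles()].
#' @param endpoints Columns to test; defaults to the composite score plus
#'   every panel column present in both tables.
#' @param B,seed,method Passed to [variance_ratio_test()].
#' @return Tibble with one row per endpoint.
#' @export
compare_within_between <- function(repro_profiles, diversity_profiles,
                                   endpoints = NULL, B = 1000, seed = NULL,
                                   method = "permutation") {
  if (is.null(endpoints)) {
    endpoints <- intersect(c("composite_score", SF_PANEL),
                           intersect(names(repro_profiles),
                                     names(diversity_profiles)))
  }
  if (!length(endpoints)) stop("no shared endpoint columns", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  dplyr::bind_rows(lapply(endpoints, function(ep) {
    dplyr::bind_cols(
      tibble::tibble(endpoint = ep),
      variance_ratio_test(repro_profiles[[ep]], diversity_profiles[[ep]],
                          B = B, method = method))
  }))
}

#' Method-of-moments variance components for a subject x day design
#'
#' One-way random-effects decomposition of a value measured on each subject
#' over repeated days: `sigma2_within` is the pooled within-subject mean
#' square and `sigma2_between = (MS_between - MS_within) / n0`, where `n0`
#' is the (possibly unbalanced) effective group size. Negative
#' between-subject estimates are truncated at zero.
#'
#' @param values Numeric vector of measurements.
#' @param subject Subject identifier, same length as `values`.
#' @return List with `sigma2_between`, `sigma2_within`, `sigma_between`,
#'   `sigma_within`.
#' @export
estimate_variance_components <- function(values, subject) {
  keep <- !is.na(values)
  values <- values[keep]; subject <- as.character(subject[keep])
  ni <- table(subject)
  k <- length(ni)
  if (k < 2 || all(ni < 2))
    stop("need >= 2 subjects and repeated measures", call. = FALSE)
  N <- length(values)
  grand <- mean(values)
  means <- tapply(values, subject, mean)
  ss_within <- sum((values - means[subject])^2)
  ms_within <- ss_within / (N - k)
  ss_between <- sum(ni * (means - grand)^2)
  ms_between <- ss_between / (k - 1)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  s2b <- max(0, (ms_between - ms_within) / n0)
  list(sigma2_between = s2b, sigma2_within = ms_within,
       sigma_between = sqrt(s2b), sigma_within = sqrt(ms_within))
}
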