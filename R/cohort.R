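#' Two-sample permutation test on the difference of group means
#'
#' The core two-group comparison: statistic `|mean(x) - mean(y)|`,
#' reference distribution built by re-assigning the pooled values to the two
#' group sizes. When the number of distinct label assignments
#' `choose(nx + ny, nx)` is at most `exhaustive_limit` the full assignment
#' set is enumerated and the p-value is the exact tail proportion (the
#' observed assignment is one of them, so p > 0); otherwise B Monte-Carlo
#' shuffles are drawn and the plus-one estimator `(b + 1) / (B + 1)` is
#' used, which never returns 0.
#'
#' @param x,y Numeric vectors (each length >= 2 after NA removal).
#' @param B Monte-Carlo permutation count.
#' @param seed Optional integer seed.
#' @param exhaustive_limit Enumerate exactly when the assignment count is at
#'   most this.
#' @return List: `statistic` (absolute mean difference), `estimate`
#'   (signed `mean(x) - mean(y)`), `p_value`, `method`
#'   (`"exhaustive"`/`"monte_carlo"`), `n_perm`.
#' @export
permutation_mean_test <- function(x, y, B = 10000, seed = NULL,
                                  exhaustive_limit = 1e4) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2)
    stop("both groups need at least two defined values", call. = FALSE)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  pool <- c(x, y)
  n <- nx + ny
  est <- mean(x) - mean(y)
  obs <- abs(est)
  n_assign <- choose(n, nx)
  if (n_assign <= exhaustive_limit) {
    idx <- utils::combn(n, nx)
    tot <- sum(pool)
    null <- abs(colSums(matrix(pool[idx], nrow = nx)) / nx -
                  (tot - colSums(matrix(pool[idx], nrow = nx))) / ny)
    p <- mean(null >= obs - 1e-12)
    list(statistic = obs, estimate = est, p_value = p,
         method = "exhaustive", n_perm = ncol(idx))
  } else {
    if (!is.null(seed)) withr::local_seed(seed)
    null <- vapply(seq_len(B), function(b) {
      i <- sample.int(n, nx)
      abs(mean(pool[i]) - mean(pool[-i]))
    }, numeric(1))
    p <- (sum(null >= obs - 1e-12) + 1) / (B + 1)
    list(statistic = obs, estimate = est, p_value = p,
         method = "monte_carlo", n_perm = B)
  }
}

#' Compare healthy and patient cohorts on one endpoint
#'
#' Two-sample comparison of a profile endpoint (a panel target's relative
#' expression or the composite score) between the two group labels. The
#' default test is the two-sided label-permutation test on the mean
#' difference ([permutation_mean_test()]); `method = "welch"` runs a Welch
#' t-test instead. The reported direction is where the *patient* group
#' lies relative to the healthy group.
#'
#' @param profiles Profile tibble with a `group` column
#'   (`"healthy"`/`"patient"`) and the endpoint column.
#' @param endpoint Column name, e.g. `"composite_score"` or a target.
#' @param method `"permutation"` (default) or `"welch"`.
#' @param B,seed,exhaustive_limit Passed to [permutation_mean_test()].
#' @return One-row tibble: `endpoint`, `n_healthy`, `n_patient`,
#'   `mean_healthy`, `mean_patient`, `statistic`, `p_value`, `direction`
#'   (`"higher_in_patient"`, `"lower_in_patient"`, `"equal"`), `method`.
#' @export
compare_groups <- function(profiles, endpoint = "composite_score",
                           method = c("permutation", "welch"),
                           B = 10000, seed = NULL, exhaustive_limit = 1e4) {
  method <- match.arg(method)
  if (!endpoint %in% names(profiles))
    stop("endpoint '", endpoint, "' not found", call. = FALSE)
  if (!"group" %in% names(profiles))
    stop("profiles must carry a group column", call. = FALSE)
  h <- profiles[[endpoint]][profiles$group == "healthy"]
  p <- profiles[[endpoint]][profiles$group == "patient"]
  h <- h[!is.na(h)]; p <- p[!is.na(p)]
  if (length(h) < 2 || length(p) < 2)
    stop("each group needs >= 2 samples with a defined '", endpoint, "'",
         call. = FALSE)
  diff_pm <- mean(p) - mean(h)
  if (method == "permutation") {
    res <- permutation_mean_test(p, h, B = B, seed = seed,
                                 exhaustive_limit = exhaustive_limit)
    stat <- res$statistic; pval <- res$p_value
    meth <- paste0("permutation_", res$method)
  } else {
    tt <- stats::t.test(p, h)
    stat <- unname(tt$statistic); pval <- tt$p.value
    meth <- "welch_t"
  }
  tibble::tibble(
    endpoint = endpoint,
    n_healthy = length(h), n_patient = length(p),
    mean_healthy = mean(h), mean_patient = mean(p),
    statistic = stat, p_value = pval,
    direction = if (diff_pm > 0) "higher_in_patient"
                else if (diff_pm < 0) "lower_in_patient" else "equal",
    method = meth)
}

#' Split a cohort into young and old strata
#'
#' Partitions profiles at an age cut: young = age < cut, old = age >= cut.
#' The default cut is the pooled median age at collection, which balances
#' the strata to within one sample. Samples with missing age are excluded
#' with a message.
#'
#' @param profiles Profile tibble with an `age` column.
#' @param cut Numeric age in years, or `"median"` (default).
#' @return List with tibbles `young` and `old`; the cut used is attached as
#'   attribute `age_cut`.
#' @export
stratify_by_age <- function(profiles, cut = "median") {
  if (!"age" %in% names(profiles))
    stop("profiles must carry an age column", call. = FALSE)
  miss <- is.na(profiles$age)
  if (any(miss)) {
    message("excluding ", sum(miss), " sample(s) with missing age")
    profiles <- profiles[!miss, ]
  }
  if (identical(cut, "median")) cut <- stats::median(profiles$age)
  if (!is.numeric(cut) || length(cut) != 1)
    stop("cut must be a single age in years or \"median\"", call. = FALSE)
  out <- list(young = profiles[profiles$age < cut, ],
              old = profiles[profiles$age >= cut, ])
  attr(out, "age_cut") <- cut
  out
}

#' Per-target and composite group comparison table
#'
#' Runs [compare_groups()] for every panel target and the composite score
#' and reports raw permutation p-values alongside Holm-adjusted ones across
#' the seven targets (the composite endpoint is a single pre-specified test
#' and is not included in the adjustment family).
#'
#' @param profiles Profile tibble with `group` and endpoint columns.
#' @param targets Panel targets to test (default [SF_PANEL]).
#' @param include_composite Also test `composite_score`.
#' @param ... Passed to [compare_groups()] (`method`, `B`, `seed`, ...).
#' @return Tibble of [compare_groups()] rows plus `p_holm` (NA for the
#'   composite row).
#' @export
per_target_summary <- function(profiles, targets = SF_PANEL,
                               include_composite = TRUE, ...) {
  targets <- intersect(targets, names(profiles))
  if (!length(targets)) stop("no target columns found", call. = FALSE)
  res <- dplyr::bind_rows(lapply(targets, function(tg)
    compare_groups(profiles, endpoint = tg, ...)))
  res$p_holm <- stats::p.adjust(res$p_value, method = "holm")
  if (include_composite && "composite_score" %in% names(profiles)) {
    comp <- compare_groups(profiles, endpoint = "composite_score", ...)
    comp$p_holm <- NA_real_
    res <- dplyr::bind_rows(res, comp)
  }
  res
}
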