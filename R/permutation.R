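#' Random-subgroup permutation test within the patient cohort
#'
#' Tests whether a labeled sub-group of patients (e.g. those on a given
#' treatment) differs from the remaining patients on the composite score.
#' The observed statistic is the absolute difference of the sub-group and
#' remainder means; its null distribution is built by drawing random
#' sub-groups of the same size uniformly without replacement from the whole
#' cohort. When the number of possible sub-groups `choose(n, k)` is at most
#' `enum_limit` the full set is enumerated and the p-value is the exact tail
#' proportion; otherwise B Monte-Carlo draws and the plus-one estimator are
#' used, so p is never 0.
#'
#' @param scores Numeric vector of composite scores for the whole cohort.
#' @param in_subgroup Logical vector marking sub-group membership; must be
#'   non-empty and proper (not the whole cohort).
#' @param B Monte-Carlo draw count (the study design uses 1000).
#' @param seed Optional integer seed.
#' @param enum_limit Enumerate exhaustively when `choose(n, k)` is at most
#'   this.
#' @param label Optional label recorded in the output.
#' @return One-row tibble: `label`, `n_subgroup`, `n_total`,
#'   `mean_subgroup`, `mean_remainder`, `observed_statistic`, `method`,
#'   `n_perm`, `p_value`, `seed`.
#' @export
subgroup_permutation_test <- function(scores, in_subgroup, B = 1000,
                                      seed = NULL, enum_limit = 1e5,
                                      label = NA_character_) {
  if (length(scores) != length(in_subgroup))
    stop("scores and in_subgroup must have the same length", call. = FALSE)
  keep <- !is.na(scores)
  scores <- scores[keep]; in_subgroup <- in_subgroup[keep]
  n <- length(scores); k <- sum(in_subgroup)
  if (k < 1 || k >= n)
    stop("sub-group must be non-empty and smaller than the cohort",
         call. = FALSE)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  m_sub <- mean(scores[in_subgroup])
  m_rem <- mean(scores[!in_subgroup])
  obs <- abs(m_sub - m_rem)
  tot <- sum(scores)
  if (choose(n, k) <= enum_limit) {
    idx <- utils::combn(n, k)
    sub_sums <- colSums(matrix(scores[idx], nrow = k))
    null <- abs(sub_sums / k - (tot - sub_sums) / (n - k))
    p <- mean(null >= obs - 1e-12)
    method <- "exhaustive"; n_perm <- ncol(idx)
  } else {
    if (!is.null(seed)) withr::local_seed(seed)
    null <- vapply(seq_len(B), function(b) {
      i <- sample.int(n, k)
      s <- sum(scores[i])
      abs(s / k - (tot - s) / (n - k))
    }, numeric(1))
    p <- (sum(null >= obs - 1e-12) + 1) / (B + 1)
    method <- "monte_carlo"; n_perm <- B
  }
  tibble::tibble(label = label, n_subgroup = k, n_total = n,
                 mean_subgroup = m_sub, mean_remainder = m_rem,
                 observed_statistic = obs, method = method,
                 n_perm = as.integer(n_perm), p_value = p,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Test a treatment sub-group against the remaining patients
#'
#' Joins expression profiles with clinical metadata on `subject_id`,
#' restricts to the patient group, marks the sub-group whose free-text
#' treatment contains `label` (case-insensitive substring, mirroring how
#' treatments are recorded as free text), and runs
#' [subgroup_permutation_test()] on the chosen endpoint.
#'
#' @param profiles Profile tibble (needs `subject_id`, `group`, endpoint).
#' @param metadata Patient metadata tibble (needs `patient_id`,
#'   `treatment`); `patient_id` is matched against `subject_id`.
#' @param label Treatment label, e.g. `"Avastin"`.
#' @param endpoint Column tested (default `"composite_score"`).
#' @param ... Passed to [subgroup_permutation_test()].
#' @return One-row tibble from [subgroup_permutation_test()].
#' @export
test_treatment_effect <- function(profiles, metadata, label,
                                  endpoint = "composite_score", ...) {
  pats <- profiles[profiles$group == "patient", ]
  if (!nrow(pats)) stop("no patient profiles", call. = FALSE)
  tx <- metadata$treatment[match(pats$subject_id, metadata$patient_id)]
  if (all(is.na(tx)))
    stop("no metadata rows match the patient subject_ids", call. = FALSE)
  in_sub <- grepl(label, tx, ignore.case = TRUE, fixed = FALSE)
  subgroup_permutation_test(pats[[endpoint]], in_sub, label = label, ...)
}

#' Scan all canonical treatment labels
#'
#' Runs [test_treatment_effect()] for each label (skipping labels whose
#' sub-group is empty or the whole cohort) and reports Holm-adjusted
#' p-values alongside the raw ones.
#'
#' @param profiles,metadata As in [test_treatment_effect()].
#' @param labels Labels to scan (default [TREATMENT_LABELS]).
#' @param ... Passed on.
#' @return Tibble with one row per testable label, plus `p_holm`.
#' @export
scan_treatment_effects <- function(profiles, metadata,
                                   labels = TREATMENT_LABELS, ...) {
  rows <- lapply(labels, function(lb) {
    tryCatch(test_treatment_effect(profiles, metadata, lb, ...),
             error = function(e) NULL)
  })
  res <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(res)) res$p_holm <- stats::p.adjust(res$p_value, method = "holm")
  res
}
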