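#' Aggregate technical replicates of one (sample, target)
#'
#' The assay measures each target in triplicate; quantification uses the
#' arithmetic mean Ct of the detected wells. Undetected wells are encoded as
#' `NA` (never as a sentinel cycle number) and simply drop out of the mean.
#'
#' @param ct Numeric vector of replicate Ct values; `NA` = undetected well.
#' @return List with `mean_ct` (NA when no well detected) and `n_detected`.
#' @examples
#' aggregate_replicates(c(24.8, 25.3, NA))
#' @export
aggregate_replicates <- function(ct) {
  if (length(ct) < 1) stop("need at least one replicate", call. = FALSE)
  if (any(ct <= 0, na.rm = TRUE))
    stop("detected Ct values must be positive", call. = FALSE)
  detected <- ct[!is.na(ct)]
  list(mean_ct = if (length(detected)) mean(detected) else NA_real_,
       n_detected = length(detected))
}

#' Comparative-Ct normalization
#'
#' Delta-Ct of a target against the endogenous control measured in the same
#' sample: `ct_target - ct_normalizer`. An undetected normalizer makes the
#' whole sample unquantifiable and is an error; an undetected target
#' propagates as `NA`.
#'
#' @param ct_target,ct_normalizer Mean Ct values in cycles (vectorized).
#' @return Delta-Ct in cycles.
#' @export
delta_ct <- function(ct_target, ct_normalizer) {
  if (any(is.na(ct_normalizer)))
    stop("normalizer undetected: sample cannot be quantified",
         call. = FALSE)
  ct_target - ct_normalizer
}

#' Relative expression under perfect doubling
#'
#' `2^(-delta_ct)`: one cycle earlier to threshold means twice the
#' transcript. Amplification efficiency is fixed at 2; the assay reports no
#' efficiency calibration.
#'
#' @param dct Delta-Ct in cycles.
#' @return Dimensionless relative expression, strictly decreasing in `dct`.
#' @export
relative_expression <- function(dct) 2^(-dct)

#' Composite panel score (summed relative expression)
#'
#' The cohort endpoint: the sum of the per-target relative expression values
#' over the panel. By default the score is strict — every panel target must
#' be detected or the score is `NA` — with an option to rescale a partial
#' sum up by `n_panel / n_detected` instead.
#'
#' @param rel_expr Numeric vector of per-target relative expression; `NA`
#'   for undetected targets.
#' @param policy `"strict"` (default) or `"rescale"`.
#' @return Dimensionless score; invariant to target ordering.
#' @examples
#' composite_score(c(1, 0.25, 2, 1, 1, 0.5, 0.25))
#' @export
composite_score <- function(rel_expr, policy = c("strict", "rescale")) {
  policy <- match.arg(policy)
  if (length(rel_expr) < 1) stop("empty profile", call. = FALSE)
  n_det <- sum(!is.na(rel_expr))
  if (n_det == 0) return(NA_real_)
  if (policy == "strict") {
    if (n_det < length(rel_expr)) return(NA_real_)
    sum(rel_expr)
  } else {
    sum(rel_expr, na.rm = TRUE) * length(rel_expr) / n_det
  }
}

#' Quantify per-sample expression profiles from a well-level Ct table
#'
#' Runs the full comparative-Ct pipeline on a long-format Ct table:
#' replicate aggregation per (sample, target), normalization against the
#' control gene, conversion to relative expression, and the composite panel
#' score. Samples whose normalizer is entirely undetected are dropped with a
#' warning.
#'
#' @param ct_data Long tibble with columns `sample_id`, `target`,
#'   `replicate`, `ct` (NA = undetected well); subject metadata columns
#'   (`subject_id`, `group`, `age`, `collection_day`) are carried through
#'   when present.
#' @param targets Panel target names (default [SF_PANEL]).
#' @param normalizer Control gene name (default [SF_NORMALIZER]).
#' @param score One of `"sum_rel_expr"` (default; sums `2^-dCt`) or
#'   `"sum_delta_ct"` (sums delta-Ct values instead).
#' @param score_policy Missing-target policy passed to [composite_score()].
#' @return A tibble with one row per sample: carried metadata, one
#'   relative-expression column per target, `n_targets_detected` and
#'   `composite_score`.
#' @export
quantify_profiles <- function(ct_data,
                              targets = SF_PANEL,
                              normalizer = SF_NORMALIZER,
                              score = c("sum_rel_expr", "sum_delta_ct"),
                              score_policy = "strict") {
  score <- match.arg(score)
  needed <- c("sample_id", "target", "replicate", "ct")
  if (!all(needed %in% names(ct_data)))
    stop("ct_data must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  if (!normalizer %in% ct_data$target)
    stop("normalizer '", normalizer, "' absent from ct_data", call. = FALSE)

  agg <- ct_data |>
    dplyr::group_by(.data$sample_id, .data$target) |>
    dplyr::summarise(mean_ct = aggregate_replicates(.data$ct)$mean_ct,
                     .groups = "drop")

  norm <- agg |>
    dplyr::filter(.data$target == normalizer) |>
    dplyr::select("sample_id", norm_ct = "mean_ct")
  bad <- norm$sample_id[is.na(norm$norm_ct)]
  if (length(bad)) {
    warning("dropping ", length(bad),
            " sample(s) with undetected normalizer: ",
            paste(bad, collapse = ", "), call. = FALSE)
    norm <- norm[!is.na(norm$norm_ct), ]
  }

  wide <- agg |>
    dplyr::filter(.data$target %in% targets) |>
    dplyr::inner_join(norm, by = "sample_id") |>
    dplyr::mutate(rel_expr =
                    relative_expression(.data$mean_ct - .data$norm_ct)) |>
    dplyr::select("sample_id", "target", "mean_ct", "norm_ct",
                  "rel_expr") |>
    dplyr::mutate(
      value = if (score == "sum_rel_expr") .data$rel_expr
              else .data$mean_ct - .data$norm_ct) |>
    dplyr::select("sample_id", "target", "rel_expr", "value")

  rel_wide <- wide |>
    dplyr::select("sample_id", "target", "rel_expr") |>
    tidyr::pivot_wider(names_from = "target", values_from = "rel_expr")
  missing_tg <- setdiff(targets, names(rel_wide))
  for (tg in missing_tg) rel_wide[[tg]] <- NA_real_
  rel_wide <- rel_wide[, c("sample_id", targets)]

  score_tbl <- wide |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_targets_detected = sum(!is.na(.data$rel_expr)),
      composite_score = composite_score(
        .data$value[match(targets, .data$target)], policy = score_policy),
      .groups = "drop")

  meta_cols <- intersect(c("subject_id", "group", "age", "collection_day"),
                         names(ct_data))
  meta <- dplyr::distinct(ct_data[, c("sample_id", meta_cols)])

  meta |>
    dplyr::inner_join(rel_wide, by = "sample_id") |>
    dplyr::inner_join(score_tbl, by = "sample_id")
}
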