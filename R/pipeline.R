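#' Run the full saliva biomarker analysis end to end
#'
#' Orchestrates the stages on file inputs: comparative-Ct quantification,
#' optional within/between-subject reproducibility analysis (run when the Ct
#' table contains repeated collection days), healthy-vs-patient comparison
#' with age stratification, treatment sub-group permutation tests, count
#' filtering and cohort metadata summary. Every output lands in `out_dir`
#' together with a JSON run manifest recording the configuration, the
#' master seed, the derived per-stage seeds and an md5 checksum of each
#' written file; identical config and seed reproduce the bundle
#' byte-for-byte.
#'
#' @param config Named list. Required: `ct_csv` (long well-level Ct table)
#'   and `out_dir`. Optional: `counts_tsv`, `metadata_csv`, `normalizer`,
#'   `targets`, `min_total` (default 3), `presence_threshold` (default 49),
#'   `age_cut` (default `"median"`), `permutations` (default 1000),
#'   `treatment_labels`, `seed` (master seed, default 1).
#' @return Invisibly, a list of the in-memory stage results plus the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  for (field in c("ct_csv", "out_dir")) {
    if (is.null(config[[field]]))
      stop("config field '", field, "' is required", call. = FALSE)
  }
  for (field in c("ct_csv", "counts_tsv", "metadata_csv")) {
    if (!is.null(config[[field]]) && !file.exists(config[[field]]))
      stop("config field '", field, "': file not found: ",
           config[[field]], call. = FALSE)
  }
  normalizer <- config$normalizer %||% SF_NORMALIZER
  targets <- config$targets %||% SF_PANEL
  seed <- as.integer(config$seed %||% 1L)
  # fixed offsets split the master seed into per-stage streams
  stage_seeds <- c(compare = seed + 1001L, permute = seed + 2002L,
                   repro = seed + 3003L)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  written <- character()
  results <- list()

  stage <- "quantify"
  res <- tryCatch({
    ct <- readr::read_csv(config$ct_csv, show_col_types = FALSE,
                          progress = FALSE)
    profiles <- quantify_profiles(ct, targets = targets,
                                  normalizer = normalizer)
    readr::write_csv(profiles, out("profiles.csv"))
    written <- c(written, out("profiles.csv"))
    profiles
  }, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
  results$profiles <- res

  if ("collection_day" %in% names(results$profiles) &&
      any(duplicated(results$profiles$subject_id))) {
    stage <- "reproducibility"
    rep_sub <- names(which.max(table(results$profiles$subject_id)))
    repro <- results$profiles[results$profiles$subject_id == rep_sub, ]
    divers <- results$profiles[!duplicated(results$profiles$subject_id) &
                                 results$profiles$subject_id != rep_sub, ]
    results$cv <- cv_report(repro, targets = targets)
    readr::write_csv(results$cv, out("cv_report.csv"))
    written <- c(written, out("cv_report.csv"))
    if (nrow(divers) >= 2) {
      results$variance_comparison <- compare_within_between(
        repro, divers, B = config$permutations %||% 1000,
        seed = stage_seeds[["repro"]])
      readr::write_csv(results$variance_comparison,
                       out("variance_comparison.csv"))
      written <- c(written, out("variance_comparison.csv"))
    }
  }

  if (all(c("healthy", "patient") %in% results$profiles$group)) {
    stage <- "compare"
    results$comparison <- per_target_summary(
      results$profiles, targets = targets,
      B = config$permutations %||% 1000, seed = stage_seeds[["compare"]])
    readr::write_csv(results$comparison, out("group_comparison.csv"))
    written <- c(written, out("group_comparison.csv"))
    strata <- stratify_by_age(results$profiles,
                              cut = config$age_cut %||% "median")
    results$age_cut <- attr(strata, "age_cut")
    ok_stratum <- function(s) all(table(s$group) >= 2) &&
      length(unique(s$group)) == 2
    results$age_strata_comparison <- dplyr::bind_rows(lapply(
      c("young", "old"), function(nm) {
        s <- strata[[nm]]
        if (!ok_stratum(s)) return(NULL)
        r <- compare_groups(s, "composite_score",
                            B = config$permutations %||% 1000,
                            seed = stage_seeds[["compare"]])
        dplyr::bind_cols(tibble::tibble(stratum = nm), r)
      }))
    if (nrow(results$age_strata_comparison)) {
      readr::write_csv(results$age_strata_comparison,
                       out("age_strata_comparison.csv"))
      written <- c(written, out("age_strata_comparison.csv"))
    }
  }

  if (!is.null(config$metadata_csv)) {
    stage <- "metadata"
    meta <- parse_metadata(config$metadata_csv)
    results$cohort_summary <- summarize_cohort(meta)
    jsonlite::write_json(results$cohort_summary,
                         out("cohort_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    written <- c(written, out("cohort_summary.json"))
    if ("patient" %in% results$profiles$group) {
      stage <- "permute"
      results$treatment_tests <- scan_treatment_effects(
        results$profiles, meta,
        labels = config$treatment_labels %||% TREATMENT_LABELS,
        B = config$permutations %||% 1000, seed = stage_seeds[["permute"]])
      if (nrow(results$treatment_tests)) {
        readr::write_csv(results$treatment_tests,
                         out("treatment_permutation.csv"))
        written <- c(written, out("treatment_permutation.csv"))
      }
    }
  }

  if (!is.null(config$counts_tsv)) {
    stage <- "filter-counts"
    counts <- read_count_table(config$counts_tsv)
    filtered <- filter_low_counts(
      exclude_biotypes(counts), min_total = config$min_total %||% 3)
    readr::write_tsv(filtered, out("counts_filtered.tsv"))
    cc <- count_columns(filtered)
    present <- call_present(filtered,
                            threshold = config$presence_threshold %||% 49,
                            sample = cc[1])
    writeLines(present, out("present_genes.txt"))
    written <- c(written, out("counts_filtered.tsv"),
                 out("present_genes.txt"))
    results$n_present <- length(present)
  }

  manifest <- list(
    config = config[setdiff(names(config), "out_dir")],
    master_seed = seed, stage_seeds = as.list(stage_seeds),
    outputs = lapply(stats::setNames(written, basename(written)),
                     function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(results, list(manifest = manifest)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
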