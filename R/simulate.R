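#' Configuration for the hierarchical Ct simulator
#'
#' Builds and validates the parameter set for [simulate_ct_dataset()]. The
#' generator emulates the statistical structure the downstream analyses
#' assume: each subject carries a stable per-target random effect (her
#' salivary "fingerprint"), each collection day adds within-subject noise,
#' and each qPCR well adds technical replicate noise. All effects live on
#' the Ct cycle scale, where one cycle corresponds to a two-fold change in
#' transcript abundance.
#'
#' The disease effect `beta_g` shifts the patient group's delta-Ct; the sign
#' convention is that a *negative* beta means fewer cycles to threshold,
#' i.e. *higher* expression in patients. The defaults encode the panel's
#' expected direction pattern (HNRNPA2B1 down in patients, the other six
#' targets up) with effect sizes calibrated so that a cohort of 36 healthy
#' versus 31 patient samples separates on the composite score at alpha =
#' 0.05 with high power.
#'
#' @param n_healthy,n_patients Number of subjects per group (>= 1; either
#'   may be 0 when simulating a single-group design).
#' @param n_repeat_days Collection days per subject (>= 1); use > 1 for
#'   reproducibility designs.
#' @param targets Character vector of panel target names.
#' @param normalizer Name of the endogenous control; must not be a target.
#' @param mu_g Named per-target baseline delta-Ct in cycles (target Ct minus
#'   normalizer Ct for a healthy subject with no random effects).
#' @param beta_g Named per-target disease effect on delta-Ct in cycles;
#'   negative = higher expression in patients.
#' @param sigma_between Between-subject SD of the per-target random effect
#'   (cycles).
#' @param sigma_within Day-to-day within-subject SD (cycles).
#' @param sigma_replicate Technical replicate SD per well (cycles).
#' @param n_replicates Wells per (sample, target); the assay runs
#'   triplicates.
#' @param normalizer_baseline Mean normalizer Ct (cycles).
#' @param age_model List with `healthy` and `patient` elements, each
#'   `c(mean =, sd =)` in years; ages are truncated below at 20.
#' @return A validated list of class `ct_sim_config`.
#' @seealso [simulate_ct_dataset()]
#' @export
ct_sim_config <- function(n_healthy = 36,
                          n_patients = 31,
                          n_repeat_days = 1,
                          targets = SF_PANEL,
                          normalizer = SF_NORMALIZER,
                          mu_g = c(HNRNPA1 = 2.5, HNRNPA2B1 = 3.0,
                                   HNRNPA3 = 4.0, HNRNPK = 3.5,
                                   HNRNPK_ex8 = 6.0, PTBP1 = 4.5,
                                   SRSF6 = 5.0),
                          beta_g = c(HNRNPA1 = -0.4, HNRNPA2B1 = 0.3,
                                     HNRNPA3 = -0.5, HNRNPK = -0.4,
                                     HNRNPK_ex8 = -0.6, PTBP1 = -0.7,
                                     SRSF6 = -0.8),
                          sigma_between = 0.8,
                          sigma_within = 0.4,
                          sigma_replicate = 0.15,
                          n_replicates = 3,
                          normalizer_baseline = 24,
                          age_model = list(healthy = c(mean = 40, sd = 12),
                                           patient = c(mean = 53, sd = 13))) {
  stopifnot(is.character(targets), length(targets) >= 1,
            is.character(normalizer), length(normalizer) == 1)
  if (normalizer %in% targets)
    stop("the normalizer gene must not appear among the panel targets",
         call. = FALSE)
  if (n_healthy < 0 || n_patients < 0 || n_healthy + n_patients < 1)
    stop("need at least one subject overall", call. = FALSE)
  if (n_repeat_days < 1) stop("n_repeat_days must be >= 1", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  for (s in c(sigma_between, sigma_within, sigma_replicate)) {
    if (!is.numeric(s) || length(s) != 1 || is.na(s) || s < 0)
      stop("all noise SDs must be single non-negative numbers",
           call. = FALSE)
  }
  mu_g <- .match_target_params(mu_g, targets, "mu_g")
  beta_g <- .match_target_params(beta_g, targets, "beta_g")
  structure(
    list(n_healthy = as.integer(n_healthy),
         n_patients = as.integer(n_patients),
         n_repeat_days = as.integer(n_repeat_days),
         targets = targets, normalizer = normalizer,
         mu_g = mu_g, beta_g = beta_g,
         sigma_between = sigma_between, sigma_within = sigma_within,
         sigma_replicate = sigma_replicate,
         n_replicates = as.integer(n_replicates),
         normalizer_baseline = normalizer_baseline,
         age_model = age_model),
    class = "ct_sim_config")
}

# Recycle a scalar parameter over the panel, or check a named vector covers
# every target.
.match_target_params <- function(x, targets, what) {
  if (length(x) == 1 && is.null(names(x))) {
    x <- stats::setNames(rep(x, length(targets)), targets)
  }
  if (is.null(names(x)) && length(x) == length(targets)) {
    names(x) <- targets
  }
  if (!all(targets %in% names(x)))
    stop(sprintf("%s must name every target", what), call. = FALSE)
  x[targets]
}

#' Simulate a long-format well-level Ct dataset
#'
#' Draws a complete qPCR experiment under the hierarchical model of
#' [ct_sim_config()]: for subject i in group x (healthy/patient), day d,
#' target g and replicate r,
#'
#' \deqn{Ct_{g,i,d,r} - Ct_{norm} = \mu_g + \beta_g 1[x_i = patient]
#'   + u_{g,i} + e_{g,i,d} + \epsilon_r}
#'
#' with u ~ N(0, sigma_between^2), e ~ N(0, sigma_within^2) and epsilon ~
#' N(0, sigma_replicate^2). The normalizer is drawn around its fixed
#' baseline with replicate noise only — it carries no disease effect. With
#' all three SDs zero the delta-Ct of every healthy sample equals `mu_g`
#' exactly.
#'
#' @param config A `ct_sim_config`.
#' @param seed Integer seed; the RNG state is restored on exit.
#' @return A tibble with one row per well: `sample_id`, `subject_id`,
#'   `group`, `age`, `collection_day`, `target`, `replicate`, `ct`.
#' @examples
#' ct <- simulate_ct_dataset(ct_sim_config(n_healthy = 2, n_patients = 1),
#'                           seed = 7)
#' head(ct)
#' @export
simulate_ct_dataset <- function(config = ct_sim_config(), seed = 1L) {
  if (!inherits(config, "ct_sim_config"))
    stop("config must be built with ct_sim_config()", call. = FALSE)
  withr::local_seed(seed)

  groups <- rep(c("healthy", "patient"),
                c(config$n_healthy, config$n_patients))
  n_sub <- length(groups)
  subject_id <- sprintf("S%03d", seq_len(n_sub))
  ages <- vapply(groups, function(g) {
    am <- config$age_model[[if (g == "healthy") "healthy" else "patient"]]
    max(20, round(stats::rnorm(1, am[["mean"]], am[["sd"]])))
  }, numeric(1))

  tg <- config$targets
  n_tg <- length(tg)
  days <- seq_len(config$n_repeat_days)
  reps <- seq_len(config$n_replicates)

  # subject-level random effects, one per (subject, target)
  u <- matrix(stats::rnorm(n_sub * n_tg, 0, config$sigma_between),
              n_sub, n_tg, dimnames = list(subject_id, tg))

  rows <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    per_day <- vector("list", length(days))
    for (d in days) {
      e <- stats::rnorm(n_tg, 0, config$sigma_within)
      dct_true <- config$mu_g + config$beta_g * (groups[i] == "patient") +
        u[i, ] + e
      ct_target <- rep(config$normalizer_baseline + dct_true,
                       each = length(reps)) +
        stats::rnorm(n_tg * length(reps), 0, config$sigma_replicate)
      ct_norm <- config$normalizer_baseline +
        stats::rnorm(length(reps), 0, config$sigma_replicate)
      per_day[[d]] <- tibble::tibble(
        sample_id = sprintf("%s_d%02d", subject_id[i], d),
        subject_id = subject_id[i],
        group = groups[i],
        age = ages[i],
        collection_day = d,
        target = c(rep(tg, each = length(reps)),
                   rep(config$normalizer, length(reps))),
        replicate = c(rep(reps, n_tg), reps),
        ct = c(ct_target, ct_norm))
    }
    rows[[i]] <- dplyr::bind_rows(per_day)
  }
  dplyr::bind_rows(rows)
}

#' Configuration for the synthetic count-table generator
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_samples Number of count columns (a pooled design has 1).
#' @param alpha Power-law tail exponent of the per-gene abundance law
#'   (larger = steeper decay, fewer high-count genes).
#' @param mean_depth Mean expected reads per gene before the long tail is
#'   applied; controls overall library depth.
#' @param excluded_biotype_fraction Proportion of genes drawn from the
#'   excluded-biotype list in `[0, 1]`.
#' @return A list of class `count_sim_config`.
#' @export
count_sim_config <- function(n_genes = 20000, n_samples = 1,
                             alpha = 1.3, mean_depth = 6,
                             excluded_biotype_fraction = 0.25) {
  if (!is.numeric(n_genes) || n_genes < 1)
    stop("n_genes must be >= 1", call. = FALSE)
  if (excluded_biotype_fraction < 0 || excluded_biotype_fraction > 1)
    stop("excluded_biotype_fraction must be in [0, 1]", call. = FALSE)
  if (alpha <= 1) stop("alpha must exceed 1", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 alpha = alpha, mean_depth = mean_depth,
                 excluded_biotype_fraction = excluded_biotype_fraction),
            class = "count_sim_config")
}

#' Simulate a gene-by-sample count table with a long-tailed abundance law
#'
#' Per-gene expected abundance follows a Pareto (power-law) distribution —
#' most genes draw a handful of reads while a thin tail reaches thousands,
#' the shape cell-free saliva RNA-seq shows — and observed counts are
#' Poisson around that expectation. A configurable fraction of genes is
#' labeled with biotypes from [EXCLUDED_BIOTYPES]; the rest are
#' protein_coding or lincRNA.
#'
#' @param config A `count_sim_config`.
#' @param seed Integer seed.
#' @return A tibble: `gene_id`, `symbol`, `biotype`, then one integer count
#'   column per sample (`pool` for a single-sample design).
#' @export
simulate_count_table <- function(config = count_sim_config(), seed = 1L) {
  if (!inherits(config, "count_sim_config"))
    stop("config must be built with count_sim_config()", call. = FALSE)
  withr::local_seed(seed)
  n <- config$n_genes
  excluded <- stats::runif(n) < config$excluded_biotype_fraction
  biotype <- ifelse(
    excluded,
    sample(EXCLUDED_BIOTYPES, n, replace = TRUE),
    sample(c("protein_coding", "lincRNA"), n, replace = TRUE,
           prob = c(0.85, 0.15)))
  # Pareto expected abundance, scaled to the requested mean depth
  lambda <- config$mean_depth * (config$alpha - 1) / config$alpha *
    stats::runif(n)^(-1 / config$alpha)
  counts <- matrix(stats::rpois(n * config$n_samples, lambda),
                   nrow = n, ncol = config$n_samples)
  cn <- if (config$n_samples == 1) "pool"
        else sprintf("sample_%02d", seq_len(config$n_samples))
  out <- tibble::tibble(
    gene_id = sprintf("GENE%05d", seq_len(n)),
    symbol = sprintf("Gene%d", seq_len(n)),
    biotype = biotype)
  for (j in seq_along(cn)) out[[cn[j]]] <- as.integer(counts[, j])
  out
}

#' Simulate a Table-1-style clinical metadata table
#'
#' Generates patient records with the same column semantics as the study's
#' clinical table: ages at saliva collection, diagnosis and (optionally)
#' death, invasive-ductal/lobular flags, HER2 status, a free-text metastasis
#' site field (possibly "Local disease" or blank), and a free-text treatment
#' string built from the canonical labels. Construction guarantees
#' `age_diagnosis <= age_collection` and, when present,
#' `age_death >= age_collection`.
#'
#' @param n_patients Number of records (>= 1).
#' @param seed Integer seed.
#' @param metastatic_rate Probability a record carries at least one distant
#'   metastasis site.
#' @return A tibble of patient records matching the [parse_metadata()]
#'   schema.
#' @export
simulate_metadata <- function(n_patients, seed = 1L, metastatic_rate = 0.7) {
  if (!is.numeric(n_patients) || n_patients < 1)
    stop("n_patients must be >= 1", call. = FALSE)
  withr::local_seed(seed)
  n <- as.integer(n_patients)
  age_dx <- pmax(25, round(stats::rnorm(n, 49, 13)))
  age_col <- age_dx + stats::rpois(n, 4)
  died <- stats::runif(n) < 0.5
  age_death <- ifelse(died, age_col + 1 + stats::rpois(n, 1), NA_real_)
  ilc <- stats::runif(n) < 0.1
  sites_pool <- c("Bone", "Liver", "Lung", "Brain", "Adrenal gland")
  metastatic <- stats::runif(n) < metastatic_rate
  sites <- vapply(seq_len(n), function(i) {
    if (metastatic[i]) {
      k <- sample(1:3, 1)
      paste(sample(sites_pool, k), collapse = ", ")
    } else if (stats::runif(1) < 0.5) "Local disease" else ""
  }, character(1))
  her2 <- ifelse(stats::runif(n) < 0.3, "+", "-")
  base_tx <- sample(c("Chemotherapy (taxol)", "Hormonal",
                      "Targeted therapy for HER2", "Chemotherapy (xeloda)"),
                    n, replace = TRUE)
  extra <- ifelse(stats::runif(n) < 0.3,
                  paste0(sample(c("Avastin", "Palbocyclib", "Afinitor"),
                                n, replace = TRUE), " and "),
                  "")
  tibble::tibble(
    patient_id = as.character(seq_len(n)),
    age_collection = as.numeric(age_col),
    age_diagnosis = as.numeric(age_dx),
    age_death = as.numeric(age_death),
    idc = !ilc,
    ilc = ilc,
    her2 = her2,
    metastasis_sites = sites,
    treatment = paste0(extra, base_tx))
}
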