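#' Path to the bundled clinical characteristics table
#'
#' The study's patient table (31 ER+ breast cancer patients: ages at saliva
#' collection, diagnosis and death, carcinoma type flags, HER2 status,
#' metastasis sites and free-text treatment), shipped as a plain CSV for the
#' worked examples.
#'
#' @return File path of the CSV inside the installed package.
#' @export
table1_path <- function() {
  system.file("extdata", "table1_patients.csv", package = "salivaSF",
              mustWork = TRUE)
}

# check-mark / cross / yes-no style cells -> logical
.parse_flag <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("√", "✓", "v", "V", "yes", "y", "TRUE", "true",
               "1")] <- TRUE
  out[x %in% c("×", "x", "X", "no", "n", "FALSE", "false", "0")] <- FALSE
  bad <- !is.na(x) & x != "" & is.na(out)
  attr(out, "bad") <- which(bad)
  out
}

.parse_her2 <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_character_, length(x))
  out[x %in% c("+", "pos", "positive")] <- "+"
  out[x %in% c("-", "−", "neg", "negative")] <- "-"
  bad <- !is.na(x) & x != "" & is.na(out)
  attr(out, "bad") <- which(bad)
  out
}

#' Parse a Table-1-style clinical metadata CSV
#'
#' Reads the patient characteristics table, normalizing check-mark/cross
#' symbols to logical IDC/ILC flags and plus/minus symbols to HER2 status.
#' Blank cells become missing values. A malformed cell raises an error
#' naming the offending data row; rows where both ages are present must
#' satisfy `age_diagnosis <= age_collection`.
#'
#' @param path CSV with headers `patient_id, age_collection, age_diagnosis,
#'   age_death, idc, ilc, her2, metastasis_sites, treatment`.
#' @return Tibble of patient records (one per row).
#' @examples
#' head(parse_metadata(table1_path()))
#' @export
parse_metadata <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  schema <- c("patient_id", "age_collection", "age_diagnosis", "age_death",
              "idc", "ilc", "her2", "metastasis_sites", "treatment")
  if (!all(schema %in% names(raw)))
    stop("metadata header must contain: ", paste(schema, collapse = ", "),
         call. = FALSE)
  if (!nrow(raw)) return(tibble::tibble(
    patient_id = character(), age_collection = numeric(),
    age_diagnosis = numeric(), age_death = numeric(),
    idc = logical(), ilc = logical(), her2 = character(),
    metastasis_sites = character(), treatment = character()))

  num <- function(col) {
    x <- trimws(raw[[col]])
    x[x == ""] <- NA
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad))
      stop("row ", bad[1], ": non-numeric ", col, " '", x[bad[1]], "'",
           call. = FALSE)
    v
  }
  age_col <- num("age_collection")
  age_dx <- num("age_diagnosis")
  age_death <- num("age_death")
  idc <- .parse_flag(raw$idc)
  if (length(attr(idc, "bad")))
    stop("row ", attr(idc, "bad")[1], ": unrecognized idc flag",
         call. = FALSE)
  ilc <- .parse_flag(raw$ilc)
  if (length(attr(ilc, "bad")))
    stop("row ", attr(ilc, "bad")[1], ": unrecognized ilc flag",
         call. = FALSE)
  her2 <- .parse_her2(raw$her2)
  if (length(attr(her2, "bad")))
    stop("row ", attr(her2, "bad")[1], ": unrecognized her2 status",
         call. = FALSE)
  attributes(her2) <- NULL
  bad_age <- which(!is.na(age_col) & !is.na(age_dx) & age_dx > age_col)
  if (length(bad_age))
    stop("row ", bad_age[1], ": age_diagnosis exceeds age_collection",
         call. = FALSE)
  sites <- raw$metastasis_sites
  sites[is.na(sites)] <- ""
  tx <- raw$treatment
  tx[is.na(tx)] <- ""
  tibble::tibble(
    patient_id = raw$patient_id,
    age_collection = age_col, age_diagnosis = age_dx,
    age_death = age_death,
    idc = as.logical(idc), ilc = as.logical(ilc), her2 = her2,
    metastasis_sites = sites, treatment = tx)
}

#' Write patient records back to the CSV schema
#'
#' Inverse of [parse_metadata()]: logical flags are written as check
#' mark/cross symbols and missing values as blank cells, so
#' `parse_metadata(write_metadata(x))` round-trips.
#'
#' @param records Patient record tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(records, path) {
  sym <- function(x) ifelse(is.na(x), "", ifelse(x, "√", "×"))
  out <- tibble::tibble(
    patient_id = records$patient_id,
    age_collection = records$age_collection,
    age_diagnosis = records$age_diagnosis,
    age_death = records$age_death,
    idc = sym(records$idc), ilc = sym(records$ilc),
    her2 = ifelse(is.na(records$her2), "", records$her2),
    metastasis_sites = records$metastasis_sites,
    treatment = records$treatment)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Classify a patient as metastatic
#'
#' A record counts as metastatic when its metastasis-site field names at
#' least one site: non-blank and not "Local disease" (case-insensitive,
#' trimmed). Blank cells count as non-metastatic.
#'
#' @param metastasis_sites Character vector of site fields.
#' @return Logical vector.
#' @export
classify_metastatic <- function(metastasis_sites) {
  s <- tolower(trimws(as.character(metastasis_sites)))
  !is.na(s) & s != "" & s != "local disease"
}

#' Summarize a patient cohort
#'
#' Cohort-level summary of a parsed metadata table: sample size, mean and
#' sample SD of age at collection (missing ages excluded with a message),
#' percent metastatic per [classify_metastatic()], and the number of
#' patients whose free-text treatment contains each canonical label
#' (case-insensitive substring).
#'
#' @param records Patient record tibble from [parse_metadata()].
#' @param treatment_labels Labels to count (default [TREATMENT_LABELS]).
#' @return List: `n`, `age_mean`, `age_sd`, `pct_metastatic` (0-100),
#'   `treatment_counts` (named integer vector).
#' @export
summarize_cohort <- function(records, treatment_labels = TREATMENT_LABELS) {
  if (!nrow(records)) stop("no records", call. = FALSE)
  ages <- records$age_collection
  if (anyNA(ages)) {
    message("excluding ", sum(is.na(ages)), " record(s) with missing age")
    ages <- ages[!is.na(ages)]
  }
  counts <- vapply(treatment_labels, function(lb)
    sum(grepl(lb, records$treatment, ignore.case = TRUE)), integer(1))
  list(n = nrow(records),
       age_mean = mean(ages),
       age_sd = if (length(ages) >= 2) stats::sd(ages) else NA_real_,
       pct_metastatic =
         100 * mean(classify_metastatic(records$metastasis_sites)),
       treatment_counts = counts)
}
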