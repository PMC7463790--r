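#' The seven-target splicing-factor panel
#'
#' Gene symbols of the salivary cell-free RNA qPCR panel quantified
#' throughout the package: six splicing factors plus the exon-8-inclusion
#' isoform of HNRNPK. `SF_NORMALIZER` is the endogenous control (PPIA) every
#' target is normalized against in the comparative-Ct calculation.
#'
#' @format `SF_PANEL` is a character vector of length 7; `SF_NORMALIZER` a
#'   length-1 character vector.
#' @export
SF_PANEL <- c("HNRNPA1", "HNRNPA2B1", "HNRNPA3", "HNRNPK",
              "HNRNPK_ex8", "PTBP1", "SRSF6")

#' @rdname SF_PANEL
#' @export
SF_NORMALIZER <- "PPIA"

#' Gene biotypes excluded before count filtering
#'
#' Annotation classes removed from RNA-seq count tables before low-count
#' filtering and presence calling (immunoglobulin/T-cell-receptor segments,
#' artifacts, and the short non-coding RNA classes).
#'
#' @format Character vector of biotype names.
#' @export
EXCLUDED_BIOTYPES <- c(
  "IG", "TR", "artifact", "miRNA", "Mt_rRNA", "Mt_tRNA", "ncRNA", "piRNA",
  "pre-miRNA", "rRNA", "ribozyme", "sRNA", "scRNA", "scaRNA", "siRNA",
  "snRNA", "snoRNA", "tRNA", "vaultRNA"
)

#' Canonical treatment labels for sub-group scans
#'
#' Labels matched case-insensitively as substrings against the free-text
#' treatment field of the clinical metadata when scanning for
#' treatment-associated differences in the composite score.
#'
#' @format Character vector.
#' @export
TREATMENT_LABELS <- c("Avastin", "Palbocyclib", "Hormonal", "Chemotherapy",
                      "HER2", "Afinitor")
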