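# Shared vocabulary and small formatting helpers.

#' Controlled vocabularies
#'
#' Label sets used across the package: variant consequence classes, gnomAD-style
#' genetic-ancestry population labels, pathogenicity classifications, inclusion
#' tiers, and the GABA-pathway marker metabolites.
#'
#' @name vocab
#' @keywords internal
NULL

consequence_classes <- c(
  "stop_gain", "frameshift", "canonical_splice", "start_loss", "stop_loss",
  "missense", "synonymous", "inframe_indel", "other"
)

population_labels <- c(
  "pan_ethnic", "african", "east_asian", "south_asian", "admixed_american",
  "ashkenazi", "remaining", "european_non_finnish", "european_finnish",
  "middle_eastern", "amish"
)

classification_levels <- c(
  "pathogenic", "likely_pathogenic", "vus", "excluded_benign",
  "excluded_frequency"
)

tier_levels <- c("base", "extended_only", "excluded")

aldh5a1_transcripts <- c("NM_001080", "NM_017040")

# Core GABA-pathway biomarkers
marker_pyrrolidinone <- "2-pyrrolidinone"
marker_guanidinobutanoate <- "4-guanidinobutanoate"
marker_argininate <- "argininate"
marker_succinamic <- "succinamic acid"
marker_succinimide <- "succinimide"

#' Marker metabolites of the GABA catabolism pathway
#'
#' @return Character vector of the five pathway biomarkers: 2-pyrrolidinone,
#'   4-guanidinobutanoate, argininate, succinamic acid, succinimide.
#' @export
gaba_markers <- function() {
  c(marker_pyrrolidinone, marker_guanidinobutanoate, marker_argininate,
    marker_succinamic, marker_succinimide)
}

# Percentage truncated (not rounded) to one decimal: 3/19 -> 15.7, 10/24 -> 41.6.
truncate_pct <- function(x) floor(x * 1000 + 1e-9) / 10

fmt_int <- function(n) {
  format(n, big.mark = ",", scientific = FALSE, trim = TRUE)
}

is_present <- function(x) !is.na(x) & nzchar(trimws(x))

check_columns <- function(df, required, what = "input") {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
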