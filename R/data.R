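# Packaged reference tables: the published diagnostic cohort and the
# published per-population carrier/prevalence estimates, stored as
# plain-text TSVs under extdata.

#' Published SSADHD diagnostic cohort
#'
#' The 24-subject case series (16 clinically ascertained subjects plus 8
#' biobank subjects with previously confirmed disease): age at sample
#' collection, sex, presenting clinical flags, urine GHB (numeric in mmol/mol
#' creatinine where measured; a logical `ghb_reported_abnormal` where only a
#' free-text abnormal report exists), and both ALDH5A1 alleles as cDNA HGVS
#' on NM_001080 with protein annotations and classifications.
#'
#' @return A tibble with one row per subject.
#' @seealso [cohort_summary()], [integrated_diagnosis()],
#'   [ssadhd_novel_variants()]
#' @export
ssadhd_cohort <- function() {
  path <- system.file("extdata", "ssadhd_cohort.tsv", package = "gabadx",
                      mustWork = TRUE)
  read_tsv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    cohort = readr::col_character(),
    age_years = readr::col_double(),
    sex = readr::col_character(),
    ethnicity = readr::col_character(),
    clinical_flags = readr::col_character(),
    urine_ghb = readr::col_double(),
    ghb_reported_abnormal = readr::col_logical(),
    imaging_suggestive = readr::col_logical(),
    allele1 = readr::col_character(),
    allele2 = readr::col_character(),
    hgvs_p1 = readr::col_character(),
    hgvs_p2 = readr::col_character(),
    class1 = readr::col_character(),
    class2 = readr::col_character()
  ), progress = FALSE)
}

#' Novel ALDH5A1 variants of the published cohort
#'
#' The three truncating variants first described in this case series; all
#' other cohort alleles were previously reported.
#'
#' @return Character vector of three cDNA HGVS strings.
#' @export
ssadhd_novel_variants <- function() {
  c("c.111_122delinsG", "c.768_784del", "c.380G>A")
}

#' Published per-population carrier and prevalence estimates
#'
#' The published "1 in N" denominators for ALDH5A1 carrier frequency and
#' SSADHD prevalence per gnomAD genetic-ancestry population, for the base
#' (known P/LP + truncating) and CADD/SpliceAI-extended variant sets, plus
#' the published fold-increase. `NA` marks populations with too few alleles
#' to estimate.
#'
#' @return A tibble with one row per population.
#' @seealso [q_from_carrier()], [hwe_estimates()]
#' @export
aldh5a1_prevalence_published <- function() {
  path <- system.file("extdata", "aldh5a1_prevalence_published.tsv",
                      package = "gabadx", mustWork = TRUE)
  read_tsv(path, col_types = readr::cols(
    population = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
}
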