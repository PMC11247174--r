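# Integrated diagnosis: combine genotype (biallelic P/LP variants),
# biochemistry (urine GHB, plasma signature) and clinical suspicion into a
# graded diagnostic status, plus cohort-level summary statistics.

#' Default clinical suspicion flags
#'
#' Presenting features that justify a "suspected" status in the absence of
#' molecular or biochemical confirmation.
#' @return Character vector of flag names.
#' @export
suspicion_flags <- function() {
  c("developmental_delay", "hypotonia", "seizures", "ataxia",
    "autistic_features", "speech_delay", "failure_to_thrive", "stroke")
}

diagnosis_levels <- c("not_supported", "suspected", "biochemically_supported",
                      "molecularly_confirmed", "comprehensively_confirmed")

#' Zygosity from two allele strings
#'
#' Alleles are normalized cDNA HGVS strings on a single transcript;
#' homozygosity is string equality.
#'
#' @param allele1,allele2 Character vectors of cDNA HGVS strings; `NA` or
#'   empty means not detected.
#' @return Character vector: `homozygous`, `compound_heterozygous`,
#'   `single_heterozygous` or `none`.
#' @export
#' @examples
#' zygosity("c.668G>A", "c.668G>A")
#' zygosity("c.1597G>A", "c.1015-2A>C")
zygosity <- function(allele1, allele2) {
  a1 <- str_squish(as.character(allele1))
  a2 <- str_squish(as.character(allele2))
  p1 <- is_present(a1)
  p2 <- is_present(a2)
  case_when(
    p1 & p2 & a1 == a2 ~ "homozygous",
    p1 & p2 ~ "compound_heterozygous",
    p1 | p2 ~ "single_heterozygous",
    .default = "none"
  )
}

#' Integrated molecular + biochemical diagnosis
#'
#' Applies the diagnostic algorithm: the molecular criterion is two
#' pathogenic/likely pathogenic alleles (homozygous or compound
#' heterozygous); the biochemical criterion is elevated urine GHB or a
#' positive plasma metabolomic signature. Both criteria met ->
#' `comprehensively_confirmed`; molecular only -> `molecularly_confirmed`;
#' biochemical only -> `biochemically_supported`; neither but a suspicion
#' flag or suggestive imaging -> `suspected`; otherwise `not_supported`.
#' Compound-heterozygous calls do not require phase confirmation.
#'
#' @param subjects Subject table with `subject_id` and any of: `allele1`,
#'   `allele2`, `class1`, `class2` (classifications of the two alleles),
#'   `urine_ghb` (numeric, mmol/mol creatinine), `ghb_reported_abnormal`
#'   (logical; free-text "elevated GHB"/"abnormal" report without a numeric
#'   value), `imaging_suggestive` (logical), `clinical_flags`
#'   (semicolon-separated flag strings).
#' @param signatures Optional signature table from [ssadhd_signature()]
#'   joined on `sample_id == subject_id`.
#' @param suspicion Clinical flags counting toward suspicion
#'   (default [suspicion_flags()]).
#' @param ghb_normal_max Upper normal bound for urine GHB (default 7).
#' @return The subject table with `zygosity`, `molecular_criterion`,
#'   `biochemical_criterion`, `diagnosis` and `rationale` columns appended.
#' @export
integrated_diagnosis <- function(subjects, signatures = NULL,
                                 suspicion = suspicion_flags(),
                                 ghb_normal_max = 7) {
  stopifnot(is.data.frame(subjects), nrow(subjects) >= 1)
  check_columns(subjects, "subject_id", "subject table")
  subjects <- as_tibble(subjects)
  n <- nrow(subjects)
  col <- function(name, default) {
    if (name %in% names(subjects)) subjects[[name]] else rep(default, n)
  }
  allele1 <- col("allele1", NA_character_)
  allele2 <- col("allele2", NA_character_)
  class1 <- col("class1", NA_character_)
  class2 <- col("class2", NA_character_)
  urine_ghb <- col("urine_ghb", NA_real_)
  ghb_text <- col("ghb_reported_abnormal", NA)
  imaging <- col("imaging_suggestive", NA)
  flags_raw <- col("clinical_flags", NA_character_)

  zyg <- zygosity(allele1, allele2)
  plp <- c("pathogenic", "likely_pathogenic")
  molecular <- zyg %in% c("homozygous", "compound_heterozygous") &
    !is.na(class1) & !is.na(class2) & class1 %in% plp & class2 %in% plp

  sig_call <- rep(NA_character_, n)
  if (!is.null(signatures)) {
    check_columns(signatures, c("sample_id", "call"), "signature table")
    sig_call <- signatures$call[match(subjects$subject_id,
                                      signatures$sample_id)]
  }
  ghb_elevated <- !is.na(urine_ghb) &
    ghb_flag(urine_ghb, ghb_normal_max) == "elevated"
  ghb_reported <- !is.na(ghb_text) & ghb_text
  biochemical <- ghb_elevated | ghb_reported |
    (!is.na(sig_call) & sig_call == "positive")

  flag_list <- map(flags_raw, function(f) {
    if (is.na(f) || !nzchar(f)) character() else str_squish(str_split(f, ";")[[1]])
  })
  suspected <- map_lgl(flag_list, ~ any(.x %in% suspicion)) |
    (!is.na(imaging) & imaging)

  no_data <- !is_present(allele1) & !is_present(allele2) &
    is.na(urine_ghb) & is.na(ghb_text) & is.na(imaging) &
    (is.na(flags_raw) | !nzchar(flags_raw)) & is.na(sig_call)
  if (any(no_data)) {
    abort(sprintf("subject(s) with no evidence in any channel: %s",
                  paste(subjects$subject_id[no_data], collapse = ", ")))
  }

  diagnosis <- case_when(
    molecular & biochemical ~ "comprehensively_confirmed",
    molecular ~ "molecularly_confirmed",
    biochemical ~ "biochemically_supported",
    suspected ~ "suspected",
    .default = "not_supported"
  )

  rationale <- pmap(
    list(molecular, ghb_elevated, ghb_reported, sig_call, suspected, zyg,
         flag_list),
    function(mol, ghb_e, ghb_r, sig, susp, zg, fl) {
      ev <- character()
      if (mol) ev <- c(ev, sprintf("biallelic P/LP variants (%s)", zg))
      if (ghb_e) ev <- c(ev, "urine GHB elevated")
      if (ghb_r) ev <- c(ev, "urine GHB/organic acids reported abnormal")
      if (!is.na(sig)) ev <- c(ev, sprintf("metabolomic signature %s", sig))
      if (susp && !mol) {
        ev <- c(ev, sprintf("clinical suspicion (%s)",
                            paste(intersect(fl, suspicion_flags()),
                                  collapse = ", ")))
      }
      if (length(ev) == 0) ev <- "no supporting evidence"
      paste(ev, collapse = "; ")
    }
  )

  subjects$zygosity <- zyg
  subjects$molecular_criterion <- molecular
  subjects$biochemical_criterion <- biochemical
  subjects$diagnosis <- diagnosis
  subjects$rationale <- unlist(rationale)
  subjects
}

#' Cohort summary statistics
#'
#' Demographics (sex counts with truncated one-decimal percentages, mean age
#' to one decimal, exact median, sample SD to two decimals), the
#' pediatric/adult split (pediatric age <= `pediatric_max`), zygosity counts
#' (subjects, with sibling pairs counted separately), and unique/novel
#' variant counts over all detected alleles.
#'
#' @param subjects Subject table with `subject_id`, `age_years`, `sex`
#'   (`M`/`F`/other), and optionally `allele1`/`allele2`.
#' @param known_variants Optional character vector of previously reported
#'   alleles; when supplied, novel counts and the truncated percentage are
#'   reported.
#' @param pediatric_max Pediatric upper age bound in years (default 18).
#' @return A one-row tibble of cohort statistics.
#' @export
cohort_summary <- function(subjects, known_variants = NULL,
                           pediatric_max = 18) {
  stopifnot(is.data.frame(subjects))
  if (nrow(subjects) == 0) abort("empty cohort")
  check_columns(subjects, c("subject_id", "age_years", "sex"), "subject table")
  ages <- subjects$age_years
  if (any(is.na(ages)) || any(ages < 0)) {
    abort("age_years must be present and non-negative for every subject")
  }
  n <- nrow(subjects)
  sex <- toupper(trimws(subjects$sex))
  n_male <- sum(sex == "M")
  n_female <- sum(sex == "F")

  alleles <- character()
  if (all(c("allele1", "allele2") %in% names(subjects))) {
    alleles <- c(subjects$allele1, subjects$allele2)
    alleles <- alleles[is_present(alleles)]
  }
  n_unique <- if (length(alleles)) unique_variant_count(alleles) else 0L
  n_hom <- if (all(c("allele1", "allele2") %in% names(subjects))) {
    sum(zygosity(subjects$allele1, subjects$allele2) == "homozygous")
  } else {
    NA_integer_
  }
  novel <- if (!is.null(known_variants) && length(alleles)) {
    u <- distinct_alleles(alleles)
    n_nov <- length(setdiff(u, distinct_alleles(known_variants)))
    list(n = n_nov, pct = novel_fraction(alleles, known_variants))
  } else {
    list(n = NA_integer_, pct = NA_real_)
  }

  tibble(
    n = n,
    n_male = n_male,
    n_female = n_female,
    pct_male = truncate_pct(n_male / n),
    pct_female = truncate_pct(n_female / n),
    mean_age = round(mean(ages), 1),
    median_age = median(ages),
    sd_age = round(sd(ages), 2),
    n_pediatric = sum(ages <= pediatric_max),
    n_adult = sum(ages > pediatric_max),
    n_homozygous = n_hom,
    n_unique_variants = n_unique,
    n_novel_variants = novel$n,
    pct_novel = novel$pct
  )
}
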