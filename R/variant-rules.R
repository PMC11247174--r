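# Rule-based ALDH5A1 variant classification and inclusion tiers.
#
# Classification rules (applied in order of precedence):
#   1. benign/likely-benign assertion          -> excluded_benign
#   2. allele frequency above the credible max -> excluded_frequency
#   3. previously reported in an affected
#      individual (and not stop-loss)          -> pathogenic
#   4. truncating consequence (stop-gain,
#      frameshift, start-loss, canonical
#      splice at +/-1 or +/-2)                 -> likely_pathogenic
#   5. everything else (incl. stop-loss)       -> vus
#
# Inclusion tiers for prevalence estimation:
#   base          P/LP variants
#   extended_only VUS rescued by computational prediction
#                 (missense CADD PHRED >= 28, or SpliceAI >= 0.2)
#   excluded      everything else

#' Classify ALDH5A1 variants by rule and assign prevalence inclusion tiers
#'
#' Applies the loss-of-function/evidence classification rules to each row of an
#' annotated variant table and stratifies variants into the inclusion tiers
#' used for carrier-frequency and disease-prevalence estimation. The base tier
#' holds pathogenic/likely pathogenic variants; the extended tier additionally
#' admits variants of uncertain significance that pass stringent computational
#' prediction cutoffs (CADD PHRED for missense, SpliceAI for potentially
#' spliceogenic variants; both cutoffs inclusive).
#'
#' @param variants A data frame with one row per variant. Required columns:
#'   `variant_id`, `consequence` (one of stop_gain, frameshift,
#'   canonical_splice, start_loss, stop_loss, missense, synonymous,
#'   inframe_indel, other), `splice_offset` (signed bp distance from the
#'   nearest canonical splice site; may be `NA` except for canonical_splice
#'   rows), `cadd_phred`, `spliceai_max`, `reported_in_affected`,
#'   `asserted_benign`, plus paired `AC_<population>` / `AN_<population>`
#'   allele-count columns.
#' @param max_credible_af Maximum credible population allele frequency for a
#'   recessive pathogenic allele; any variant whose frequency exceeds this in
#'   any population is excluded (default 0.01).
#' @param cadd_cutoff CADD PHRED cutoff for the extended missense branch
#'   (default 28, inclusive).
#' @param spliceai_cutoff SpliceAI max delta cutoff for the extended
#'   spliceogenic branch (default 0.2, inclusive).
#'
#' @return The input as a tibble with `classification` and `inclusion_tier`
#'   columns appended.
#' @seealso [read_variant_table()], [prevalence_table()]
#' @export
#' @examples
#' variants <- tibble::tibble(
#'   variant_id = c("v1", "v2", "v3"),
#'   consequence = c("stop_gain", "missense", "missense"),
#'   splice_offset = NA_real_,
#'   cadd_phred = c(NA, 29.1, 21.0),
#'   spliceai_max = NA_real_,
#'   reported_in_affected = c(TRUE, FALSE, FALSE),
#'   asserted_benign = FALSE,
#'   AC_pan_ethnic = c(3L, 10L, 2L),
#'   AN_pan_ethnic = 1000000L
#' )
#' classify_variants(variants)
classify_variants <- function(variants, max_credible_af = 0.01,
                              cadd_cutoff = 28, spliceai_cutoff = 0.2) {
  stopifnot(is.data.frame(variants), max_credible_af > 0)
  variants <- as_tibble(variants)
  check_columns(variants, c(
    "variant_id", "consequence", "splice_offset", "cadd_phred",
    "spliceai_max", "reported_in_affected", "asserted_benign"
  ), "variant table")

  bad_csq <- setdiff(unique(variants$consequence), consequence_classes)
  if (length(bad_csq) > 0) {
    abort(sprintf("unknown consequence class(es): %s",
                  paste(bad_csq, collapse = ", ")))
  }
  sai <- variants$spliceai_max
  if (any(!is.na(sai) & (sai < 0 | sai > 1))) {
    abort("spliceai_max must lie in [0, 1]")
  }
  no_offset <- variants$consequence == "canonical_splice" &
    is.na(variants$splice_offset)
  if (any(no_offset)) {
    abort(sprintf(
      "canonical_splice variant(s) with absent splice_offset (cannot apply the +/-1/2 window): %s",
      paste(variants$variant_id[no_offset], collapse = ", ")
    ))
  }

  max_af <- max_population_af(variants)

  classification <- case_when(
    variants$asserted_benign ~ "excluded_benign",
    max_af > max_credible_af ~ "excluded_frequency",
    variants$reported_in_affected & variants$consequence != "stop_loss" ~
      "pathogenic",
    variants$consequence %in% c("stop_gain", "frameshift", "start_loss") ~
      "likely_pathogenic",
    variants$consequence == "canonical_splice" &
      abs(variants$splice_offset) %in% c(1, 2) ~ "likely_pathogenic",
    .default = "vus"
  )

  cadd_ok <- !is.na(variants$cadd_phred) & variants$cadd_phred >= cadd_cutoff
  sai_ok <- !is.na(sai) & sai >= spliceai_cutoff
  inclusion_tier <- case_when(
    classification %in% c("pathogenic", "likely_pathogenic") ~ "base",
    classification == "vus" &
      ((variants$consequence == "missense" & cadd_ok) | sai_ok) ~
      "extended_only",
    .default = "excluded"
  )

  variants$classification <- classification
  variants$inclusion_tier <- inclusion_tier
  variants
}

# Highest allele frequency of each variant across all AC_/AN_ column pairs
# (NA pairs contribute nothing; a variant with no data has max AF 0).
max_population_af <- function(variants) {
  pops <- detect_populations(variants)
  if (length(pops) == 0) {
    return(rep(0, nrow(variants)))
  }
  af <- vapply(pops, function(p) {
    ac <- variants[[paste0("AC_", p)]]
    an <- variants[[paste0("AN_", p)]]
    ifelse(is.na(ac) | is.na(an) | an == 0, 0, ac / an)
  }, numeric(nrow(variants)))
  if (nrow(variants) == 1) af <- matrix(af, nrow = 1)
  apply(af, 1, max)
}

detect_populations <- function(variants) {
  ac_pops <- sub("^AC_", "", grep("^AC_", names(variants), value = TRUE))
  an_pops <- sub("^AN_", "", grep("^AN_", names(variants), value = TRUE))
  intersect(ac_pops, an_pops)
}

#' Read an annotated variant table (TSV)
#'
#' Reads a tab-separated variant table of the shape exported from population
#' databases (one row per variant; per-population `AC_<pop>`/`AN_<pop>` pairs)
#' and validates every field. Rows violating an invariant are rejected with
#' messages naming the offending data row.
#'
#' @param path Path to a tab-separated file with header columns `variant_id`,
#'   `transcript`, `hgvs_c`, `hgvs_p`, `consequence`, `splice_offset`,
#'   `cadd_phred`, `spliceai_max`, `reported_in_affected`, `asserted_benign`,
#'   and at least one `AC_<pop>`/`AN_<pop>` pair. Empty strings denote absent
#'   values.
#'
#' @return A typed tibble of validated variant records.
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
  required <- c("variant_id", "transcript", "hgvs_c", "hgvs_p", "consequence",
                "splice_offset", "cadd_phred", "spliceai_max",
                "reported_in_affected", "asserted_benign")
  check_columns(raw, required, sprintf("variant table '%s'", path))
  pops <- detect_populations(raw)
  if (length(pops) == 0) {
    abort(sprintf("variant table '%s' has no AC_<pop>/AN_<pop> column pairs", path))
  }
  if (nrow(raw) == 0) {
    out <- tibble(
      variant_id = character(), transcript = character(),
      hgvs_c = character(), hgvs_p = character(), consequence = character(),
      splice_offset = numeric(), cadd_phred = numeric(),
      spliceai_max = numeric(), reported_in_affected = logical(),
      asserted_benign = logical()
    )
    for (p in pops) {
      out[[paste0("AC_", p)]] <- integer()
      out[[paste0("AN_", p)]] <- integer()
    }
    return(out)
  }

  problems <- character()
  note <- function(row, msg) {
    problems <<- c(problems, sprintf("row %d: %s", row, msg))
  }
  parse_num <- function(col, row_check = NULL) {
    x <- trimws(raw[[col]] %||% NA_character_)
    x[!is.na(x) & x == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    for (r in bad) note(r, sprintf("malformed numeric value '%s' in %s", x[r], col))
    out
  }
  parse_lgl <- function(col) {
    x <- toupper(trimws(raw[[col]]))
    x[is.na(x) | x == ""] <- "FALSE"
    out <- x %in% c("TRUE", "T", "1", "YES")
    bad <- which(!x %in% c("TRUE", "T", "1", "YES", "FALSE", "F", "0", "NO"))
    for (r in bad) note(r, sprintf("malformed logical value in %s", col))
    out
  }

  out <- tibble(
    variant_id = trimws(raw$variant_id),
    transcript = trimws(raw$transcript),
    hgvs_c = trimws(raw$hgvs_c),
    hgvs_p = ifelse(is.na(raw$hgvs_p), "", trimws(raw$hgvs_p)),
    consequence = trimws(raw$consequence),
    splice_offset = parse_num("splice_offset"),
    cadd_phred = parse_num("cadd_phred"),
    spliceai_max = parse_num("spliceai_max"),
    reported_in_affected = parse_lgl("reported_in_affected"),
    asserted_benign = parse_lgl("asserted_benign")
  )

  for (r in seq_len(nrow(out))) {
    if (!out$consequence[r] %in% consequence_classes) {
      note(r, sprintf("unknown consequence '%s'", out$consequence[r]))
    }
    tx <- sub("\\..*$", "", out$transcript[r])
    if (!tx %in% aldh5a1_transcripts) {
      note(r, sprintf("transcript '%s' is not one of %s", out$transcript[r],
                      paste(aldh5a1_transcripts, collapse = "/")))
    }
    if (!is.na(out$cadd_phred[r]) && out$cadd_phred[r] < 0) {
      note(r, "cadd_phred must be non-negative")
    }
    if (!is.na(out$spliceai_max[r]) &&
        (out$spliceai_max[r] < 0 || out$spliceai_max[r] > 1)) {
      note(r, "spliceai_max outside [0, 1]")
    }
  }

  for (p in pops) {
    ac <- parse_num(paste0("AC_", p))
    an <- parse_num(paste0("AN_", p))
    for (r in seq_len(nrow(out))) {
      if (!is.na(ac[r]) && ac[r] < 0) note(r, sprintf("AC_%s is negative", p))
      if (!is.na(an[r]) && an[r] <= 0) note(r, sprintf("AN_%s must be positive", p))
      if (!is.na(ac[r]) && !is.na(an[r]) && ac[r] > an[r]) {
        note(r, sprintf("AC_%s (%g) exceeds AN_%s (%g)", p, ac[r], p, an[r]))
      }
    }
    out[[paste0("AC_", p)]] <- ac
    out[[paste0("AN_", p)]] <- an
  }

  dup <- duplicated(out$variant_id)
  if (any(dup)) {
    for (r in which(dup)) note(r, sprintf("duplicate variant_id '%s'", out$variant_id[r]))
  }
  if (length(problems) > 0) {
    abort(paste(c(sprintf("invalid variant table '%s':", path), problems),
                collapse = "\n"))
  }
  out
}

#' Count distinct variant alleles and the fraction that is novel
#'
#' Variant identity is the (whitespace-trimmed, case-preserved) cDNA-level HGVS
#' string on a single transcript: discrepant protein annotations of the same
#' nucleotide change do not split a variant.
#'
#' @param alleles Character vector of cDNA HGVS strings (e.g. both allele
#'   columns of a cohort table stacked); `NA`/empty entries are dropped.
#' @param known_set For [novel_fraction()], character vector of previously
#'   reported alleles.
#'
#' @return `unique_variant_count()`: integer count of distinct alleles.
#'   `novel_fraction()`: percentage of distinct alleles absent from
#'   `known_set`, truncated to one decimal (e.g. 3 of 19 -> 15.7).
#' @export
#' @examples
#' unique_variant_count(c("c.668G>A", "c.668G>A", "c.1597G>A"))
#' novel_fraction(c("c.668G>A", "c.1597G>A"), known_set = "c.1597G>A")
unique_variant_count <- function(alleles) {
  u <- distinct_alleles(alleles)
  if (length(u) == 0) abort("no non-missing alleles supplied")
  length(u)
}

#' @rdname unique_variant_count
#' @export
novel_fraction <- function(alleles, known_set) {
  u <- distinct_alleles(alleles)
  if (length(u) == 0) abort("no non-missing alleles supplied")
  known <- distinct_alleles(known_set)
  n_novel <- length(setdiff(u, known))
  truncate_pct(n_novel / length(u))
}

distinct_alleles <- function(alleles) {
  x <- str_squish(as.character(alleles))
  unique(x[!is.na(x) & nzchar(x)])
}
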