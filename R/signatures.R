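# Biomarker signature calls for the two GABA-catabolism disorders.
#
# SSADHD plasma: core markers 2-pyrrolidinone and 4-guanidinobutanoate; both
# elevated (z >= 2) in pediatric disease, while adults show normal
# 2-pyrrolidinone with high-normal 4-guanidinobutanoate (z >= 1.7), hence the
# supportive band. SSADHD urine: 4-guanidinobutanoate + succinimide
# (2-pyrrolidinone carries no weight in urine). GABA-TD plasma:
# 2-pyrrolidinone + succinamic acid.

marker_lookup <- function(ztbl, markers) {
  check_columns(ztbl, c("sample_id", "metabolite", "z", "flag"),
                "z-score table")
  get <- function(sub, m, col) {
    i <- which(sub$metabolite == m)
    if (length(i) == 0) {
      if (col == "flag") "not_reported" else NA_real_
    } else {
      sub[[col]][i[1]]
    }
  }
  list(get = get)
}

call_one_signature <- function(sub, core, get, supportive_extra = NULL) {
  flags <- vapply(core, function(m) get(sub, m, "flag"), character(1))
  if (any(flags == "not_reported")) {
    return(list(call = "indeterminate",
                evidence = sprintf("core marker not reported: %s",
                                   paste(core[flags == "not_reported"],
                                         collapse = ", "))))
  }
  n_high <- sum(flags == "high")
  if (n_high == length(core)) {
    return(list(call = "positive",
                evidence = sprintf("all core markers high (%s)",
                                   paste(core, collapse = ", "))))
  }
  if (n_high >= 1) {
    return(list(call = "supportive",
                evidence = sprintf("core marker high: %s",
                                   paste(core[flags == "high"], collapse = ", "))))
  }
  if (!is.null(supportive_extra)) {
    extra <- supportive_extra(sub)
    if (!is.null(extra)) return(list(call = "supportive", evidence = extra))
  }
  list(call = "negative", evidence = "no core marker elevated")
}

signature_table <- function(ztbl, disease, core_for, allowed_specimens,
                            supportive_extra = NULL) {
  check_columns(ztbl, c("sample_id", "specimen", "metabolite", "z", "flag"),
                "z-score table")
  bad <- setdiff(unique(ztbl$specimen), allowed_specimens)
  if (length(bad) > 0) {
    abort(sprintf("unsupported specimen type(s) for the %s signature: %s",
                  disease, paste(bad, collapse = ", ")))
  }
  lk <- marker_lookup(ztbl, NULL)
  split_samples <- split(ztbl, ztbl$sample_id)
  map(split_samples, function(sub) {
    specimen <- sub$specimen[1]
    res <- call_one_signature(sub, core_for(specimen), lk$get,
                              supportive_extra =
                                if (specimen == "plasma") supportive_extra)
    tibble(sample_id = sub$sample_id[1], specimen = specimen,
           disease = disease, call = res$call, evidence = res$evidence)
  }) |> list_rbind()
}

#' Call the SSADHD biomarker signature
#'
#' Plasma: positive requires both core markers (2-pyrrolidinone and
#' 4-guanidinobutanoate) flagged high (z >= 2); a single high core marker, or
#' 4-guanidinobutanoate at or above the adult attenuation band
#' (`adult_band`, default z >= 1.7), yields a supportive call; elevated
#' argininate or succinamic acid is reported as corroborating evidence.
#' Urine: positive requires 4-guanidinobutanoate and succinimide both high;
#' 2-pyrrolidinone carries no weight in urine. A missing core marker makes
#' the call indeterminate. CSF is unsupported.
#'
#' @param ztbl Long z-score table from [metabolite_zscores()] with a
#'   `specimen` column (`plasma` or `urine`).
#' @param adult_band Supportive threshold for plasma 4-guanidinobutanoate
#'   (default 1.7 SD).
#' @return A tibble with one row per sample: `sample_id`, `specimen`,
#'   `disease`, `call` (`positive`/`supportive`/`negative`/`indeterminate`),
#'   `evidence`.
#' @export
ssadhd_signature <- function(ztbl, adult_band = 1.7) {
  core_for <- function(specimen) {
    if (specimen == "plasma") {
      c(marker_pyrrolidinone, marker_guanidinobutanoate)
    } else {
      c(marker_guanidinobutanoate, marker_succinimide)
    }
  }
  lk <- marker_lookup(ztbl, NULL)
  supportive_extra <- function(sub) {
    z4gb <- lk$get(sub, marker_guanidinobutanoate, "z")
    if (is.na(z4gb) || z4gb < adult_band) {
      return(NULL)
    }
    co <- c(marker_argininate, marker_succinamic)
    co_high <- co[vapply(co, function(m) {
      identical(lk$get(sub, m, "flag"), "high")
    }, logical(1))]
    msg <- sprintf("4-guanidinobutanoate mildly elevated (z = %.2f)", z4gb)
    if (length(co_high) > 0) {
      msg <- paste0(msg, "; corroborated by high ",
                    paste(co_high, collapse = ", "))
    }
    msg
  }
  signature_table(ztbl, disease = "SSADHD", core_for = core_for,
                  allowed_specimens = c("plasma", "urine"),
                  supportive_extra = supportive_extra)
}

#' Call the GABA transaminase deficiency (GABA-TD) plasma signature
#'
#' Positive requires both 2-pyrrolidinone and succinamic acid flagged high
#' (z >= 2); exactly one high core marker is supportive; a missing core
#' marker makes the call indeterminate. Only plasma is supported.
#'
#' @inheritParams ssadhd_signature
#' @return A tibble as in [ssadhd_signature()], with `disease = "GABA_TD"`.
#' @export
gabat_signature <- function(ztbl) {
  core_for <- function(specimen) c(marker_pyrrolidinone, marker_succinamic)
  signature_table(ztbl, disease = "GABA_TD", core_for = core_for,
                  allowed_specimens = "plasma")
}

#' Flag urine GHB relative to the normal range
#'
#' Urine 4-hydroxybutyrate (GHB) in mmol/mol creatinine; the normal range is
#' 0-7, so values strictly above `normal_max` are flagged elevated.
#'
#' @param value GHB in mmol/mol creatinine (vectorized, non-negative; `NA`
#'   propagates).
#' @param normal_max Upper bound of the normal range (default 7).
#' @return Character vector of `"elevated"` / `"normal"`.
#' @export
#' @examples
#' ghb_flag(c(4323, 7, 0.5))
ghb_flag <- function(value, normal_max = 7) {
  if (any(!is.na(value) & value < 0)) abort("GHB values must be non-negative")
  ifelse(is.na(value), NA_character_,
         ifelse(value > normal_max, "elevated", "normal"))
}
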