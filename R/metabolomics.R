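# Untargeted-metabolomics z-score pipeline:
#   raw intensities -> (urine: creatinine normalization) -> anchor
#   normalization per batch -> natural-log transform -> z-scores against a
#   reference cohort -> abnormality flags at |z| >= 2 (inclusive).
#
# Intensity matrices are wide tibbles (one `sample_id` column + one column per
# metabolite); sample metadata travels in a separate sample sheet keyed by
# `sample_id`.

metabolite_cols <- function(intensities) {
  setdiff(names(intensities), "sample_id")
}

join_samples <- function(intensities, samples, need = character()) {
  check_columns(intensities, "sample_id", "intensity matrix")
  check_columns(samples, c("sample_id", need), "sample sheet")
  missing <- setdiff(intensities$sample_id, samples$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("sample sheet lacks entries for: %s",
                  paste(missing, collapse = ", ")))
  }
  samples[match(intensities$sample_id, samples$sample_id), , drop = FALSE]
}

#' Normalize urine metabolite intensities to creatinine
#'
#' Divides every metabolite value of a urine sample by that sample's
#' creatinine concentration, putting intensities on a per-mmol-creatinine
#' scale so that urine dilution cancels.
#'
#' @param intensities Wide intensity tibble (`sample_id` + metabolite
#'   columns), raw values `>= 0`.
#' @param samples Sample sheet with `sample_id` and positive `creatinine`.
#' @return The intensity tibble with each row divided by its creatinine.
#' @export
creatinine_normalize <- function(intensities, samples) {
  meta <- join_samples(intensities, samples, need = "creatinine")
  cr <- meta$creatinine
  if (any(is.na(cr) | cr <= 0)) {
    abort(sprintf("creatinine must be positive for every sample (bad: %s)",
                  paste(intensities$sample_id[is.na(cr) | cr <= 0],
                        collapse = ", ")))
  }
  out <- intensities
  for (m in metabolite_cols(out)) out[[m]] <- out[[m]] / cr
  out
}

#' Anchor-normalize an intensity matrix batch by batch
#'
#' Semiquantification against invariant anchor specimens: each value is
#' divided by the median intensity of that metabolite across the anchor
#' samples of the same analytical batch, so anchor medians become 1 and any
#' batch-wide multiplicative factor cancels.
#'
#' @param intensities Wide intensity tibble (`sample_id` + metabolite
#'   columns).
#' @param samples Sample sheet with `sample_id`, `batch` and logical
#'   `is_anchor`; every batch must contain at least one anchor.
#' @return The anchor-normalized intensity tibble. Metabolites with no
#'   non-missing anchor value in a batch are set to `NA` in that batch, with a
#'   warning.
#' @export
anchor_normalize <- function(intensities, samples) {
  meta <- join_samples(intensities, samples, need = c("batch", "is_anchor"))
  batches <- unique(meta$batch)
  no_anchor <- batches[!batches %in% unique(meta$batch[meta$is_anchor])]
  if (length(no_anchor) > 0) {
    abort(sprintf("batch(es) without any anchor sample: %s",
                  paste(no_anchor, collapse = ", ")))
  }
  mets <- metabolite_cols(intensities)
  out <- intensities
  dropped <- character()
  for (b in batches) {
    in_batch <- meta$batch == b
    anchors <- in_batch & meta$is_anchor
    for (m in mets) {
      med <- median(intensities[[m]][anchors], na.rm = TRUE)
      if (is.na(med) || med <= 0) {
        out[[m]][in_batch] <- NA_real_
        dropped <- c(dropped, sprintf("%s (batch %s)", m, b))
      } else {
        out[[m]][in_batch] <- intensities[[m]][in_batch] / med
      }
    }
  }
  if (length(dropped) > 0) {
    warn(sprintf("no usable anchor coverage, values set missing: %s",
                 paste(dropped, collapse = "; ")))
  }
  out
}

#' Build reference-population statistics
#'
#' Per-metabolite location and scale of the log-transformed, anchor-normalized
#' reference cohort: mean and sample standard deviation (denominator n - 1) of
#' `log(value)` (natural log).
#'
#' @param normalized Anchor-normalized intensity tibble.
#' @param samples Optional sample sheet with logical `is_reference`; when
#'   supplied only reference samples are used, otherwise every row of
#'   `normalized` is treated as reference.
#' @return A tibble with `metabolite`, `mean_log`, `sd_log`, `n_obs`, plus an
#'   `n_reference` attribute (reference cohort size). Metabolites with zero
#'   variance are excluded with a warning; metabolites with fewer than two
#'   non-missing values are an error.
#' @export
build_reference <- function(normalized, samples = NULL) {
  check_columns(normalized, "sample_id", "intensity matrix")
  if (!is.null(samples)) {
    meta <- join_samples(normalized, samples, need = "is_reference")
    normalized <- normalized[meta$is_reference, , drop = FALSE]
  }
  if (nrow(normalized) < 2) abort("reference cohort must contain >= 2 samples")
  mets <- metabolite_cols(normalized)
  stats <- map(mets, function(m) {
    v <- normalized[[m]]
    v <- v[!is.na(v)]
    if (any(v <= 0)) {
      warn(sprintf("non-positive reference values dropped for %s", m))
      v <- v[v > 0]
    }
    if (length(v) < 2) {
      abort(sprintf("metabolite %s has fewer than 2 non-missing reference values", m))
    }
    lv <- log(v)
    tibble(metabolite = m, mean_log = mean(lv), sd_log = sd(lv),
           n_obs = length(lv))
  }) |> list_rbind()
  constant <- stats$sd_log <= 0
  if (any(constant)) {
    warn(sprintf("constant metabolite(s) excluded from reference: %s",
                 paste(stats$metabolite[constant], collapse = ", ")))
    stats <- stats[!constant, , drop = FALSE]
  }
  attr(stats, "n_reference") <- nrow(normalized)
  stats
}

#' Score samples against a reference population
#'
#' Computes per-metabolite z-scores `z = (log(value) - mean_log) / sd_log`
#' and abnormality flags: `high` when `z >= threshold`, `low` when
#' `z <= -threshold` (both inclusive, default threshold 2 SD), `normal`
#' otherwise, `not_reported` where the value is missing or non-positive.
#'
#' @param normalized Anchor-normalized intensity tibble for the samples to
#'   score.
#' @param ref Reference statistics from [build_reference()].
#' @param samples Optional sample sheet; if supplied, `specimen`,
#'   `age_years`, `batch` and `group` columns (when present) are carried into
#'   the output.
#' @param threshold Abnormality threshold in SD units (default 2).
#' @return A long tibble with one row per sample x metabolite covered by the
#'   reference: `sample_id`, `metabolite`, `z`, `flag`, plus any carried
#'   metadata columns.
#' @export
metabolite_zscores <- function(normalized, ref, samples = NULL, threshold = 2) {
  check_columns(normalized, "sample_id", "intensity matrix")
  check_columns(ref, c("metabolite", "mean_log", "sd_log"), "reference stats")
  mets <- intersect(metabolite_cols(normalized), ref$metabolite)
  if (length(mets) == 0) {
    abort("reference statistics cover none of the metabolites in the matrix")
  }
  long <- pivot_longer(normalized[, c("sample_id", mets)],
                       cols = -"sample_id",
                       names_to = "metabolite", values_to = "value")
  long <- left_join(long, ref[, c("metabolite", "mean_log", "sd_log")],
                    by = "metabolite")
  nonpos <- !is.na(long$value) & long$value <= 0
  if (any(nonpos)) {
    warn(sprintf("%d non-positive value(s) flagged not_reported", sum(nonpos)))
    long$value[nonpos] <- NA_real_
  }
  long$z <- (log(long$value) - long$mean_log) / long$sd_log
  long$flag <- case_when(
    is.na(long$z) ~ "not_reported",
    long$z >= threshold ~ "high",
    long$z <= -threshold ~ "low",
    .default = "normal"
  )
  out <- long[, c("sample_id", "metabolite", "z", "flag")]
  if (!is.null(samples)) {
    carry <- intersect(c("specimen", "age_years", "batch", "group"),
                       names(samples))
    out <- left_join(out, samples[, c("sample_id", carry)], by = "sample_id")
  }
  out
}
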