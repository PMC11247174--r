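# Cumulative pathogenic allele frequency and Hardy-Weinberg estimates.
#
# For a recessive disorder with cumulative pathogenic allele frequency q,
# Hardy-Weinberg equilibrium gives carrier frequency 2q(1-q) and disease
# prevalence q^2. The exact carrier form (not the 2q approximation) is used
# throughout: it is the form that round-trips published carrier/prevalence
# pairs at their printed precision.

#' Cumulative pathogenic allele frequency per population and tier
#'
#' Sums per-variant allele frequencies (AC/AN) over the qualifying variants of
#' each inclusion tier: the `base` tier sums pathogenic/likely pathogenic
#' variants; `base_plus_extended` additionally includes `extended_only`
#' variants (VUS admitted by CADD/SpliceAI prediction). Alleles are assumed
#' unlinked and phase is ignored, the standard treatment for ultra-rare
#' recessive prevalence estimation.
#'
#' @param classified A classified variant table from [classify_variants()]
#'   (must carry `inclusion_tier` and `AC_<pop>`/`AN_<pop>` columns).
#' @param population Optional character vector restricting to specific
#'   population labels; default all populations present in the table.
#' @param tier Tiers to compute; any of `"base"`, `"base_plus_extended"`.
#'
#' @return A tibble with columns `population`, `tier`, `q` (cumulative
#'   pathogenic allele frequency), `n_variants` (qualifying variants with
#'   AC > 0 in that population) and `n_absent` (qualifying variants with no
#'   allele data for that population; these contribute 0).
#' @export
cumulative_frequencies <- function(classified,
                                   population = NULL,
                                   tier = c("base", "base_plus_extended")) {
  stopifnot(is.data.frame(classified))
  check_columns(classified, "inclusion_tier", "classified variant table")
  tier <- match.arg(tier, several.ok = TRUE)
  pops <- detect_populations(classified)
  if (length(pops) == 0) abort("no AC_<pop>/AN_<pop> column pairs found")
  if (!is.null(population)) {
    unknown <- setdiff(population, pops)
    if (length(unknown) > 0) {
      abort(sprintf("unknown population label(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    pops <- population
  }

  grid <- tidyr::expand_grid(population = pops, tier = tier)
  res <- pmap(grid, function(population, tier) {
    keep <- if (tier == "base") "base" else c("base", "extended_only")
    sub <- classified[classified$inclusion_tier %in% keep, , drop = FALSE]
    ac <- sub[[paste0("AC_", population)]]
    an <- sub[[paste0("AN_", population)]]
    absent <- is.na(ac) | is.na(an)
    af <- ifelse(absent, 0, ac / an)
    tibble(
      population = population, tier = tier,
      q = sum(af),
      n_variants = sum(!absent & ac > 0),
      n_absent = sum(absent)
    )
  })
  res <- list_rbind(res)
  if (sum(res$n_absent) > 0) {
    inform(sprintf(
      "%d qualifying variant/population combinations had no allele data and contributed 0",
      sum(res$n_absent)
    ))
  }
  res
}

#' Hardy-Weinberg carrier frequency and disease prevalence from q
#'
#' @param q Cumulative pathogenic allele frequency (vectorized), in
#'   `[0, 0.5]`.
#' @param sig_figs Significant figures for the formatted "1/N" strings
#'   (default 3).
#'
#' @return A tibble with columns `q`, `carrier_frequency` (`2q(1-q)`),
#'   `disease_prevalence` (`q^2`), and formatted `carrier_one_in` /
#'   `prevalence_one_in` strings (`"not estimable"` when `q = 0`).
#' @export
#' @examples
#' hwe_estimates(q_from_carrier(1 / 376))
hwe_estimates <- function(q, sig_figs = 3) {
  if (any(is.na(q)) || any(q < 0 | q > 0.5)) {
    abort("q must lie in [0, 0.5]")
  }
  carrier <- 2 * q * (1 - q)
  prevalence <- q^2
  fmt <- function(f) {
    vapply(f, function(x) {
      if (x <= 0) "not estimable" else format_one_in_n(x, sig_figs)
    }, character(1))
  }
  tibble(
    q = q,
    carrier_frequency = carrier,
    disease_prevalence = prevalence,
    carrier_one_in = fmt(carrier),
    prevalence_one_in = fmt(prevalence)
  )
}

#' Invert a carrier frequency to the allele frequency q
#'
#' Solves `2q(1-q) = carrier` for the smaller root,
#' `q = (1 - sqrt(1 - 2 carrier)) / 2`. Used to reconstruct prevalence from a
#' published carrier frequency.
#'
#' @param carrier Carrier frequency in `(0, 0.5]` (vectorized).
#' @return The allele frequency `q`.
#' @export
#' @examples
#' q <- q_from_carrier(1 / 376)
#' format_one_in_n(q^2, sig_figs = 3)
q_from_carrier <- function(carrier) {
  if (any(is.na(carrier)) || any(carrier <= 0 | carrier > 0.5)) {
    abort("carrier must lie in (0, 0.5]")
  }
  (1 - sqrt(1 - 2 * carrier)) / 2
}

#' Fold-increase in prevalence between inclusion tiers
#'
#' Ratio of the base-tier "1 in N" prevalence denominator to the extended-tier
#' denominator, reported to one decimal. With the extended variant set a
#' superset of the base set the ratio is >= 1.
#'
#' @param n_base,n_extended "1 in N" prevalence denominators (N, not the
#'   frequency) for the base and extended tiers.
#' @return The fold-increase, rounded to one decimal.
#' @export
#' @examples
#' fold_increase(1000000, 77000) # 13.0
fold_increase <- function(n_base, n_extended) {
  if (any(is.na(n_extended)) || any(n_extended <= 0)) {
    abort("n_extended must be positive")
  }
  if (any(is.na(n_base)) || any(n_base <= 0)) {
    abort("n_base must be positive")
  }
  round(n_base / n_extended, 1)
}

#' Format a frequency as "1/N"
#'
#' N = 1/freq is displayed exactly (thousands-separated) when it is an
#' integer, otherwise rounded to `sig_figs` significant figures.
#'
#' @param freq Frequency in `(0, 1]`.
#' @param sig_figs Significant figures in `{1, 2, 3}` (default 3).
#' @return A string such as `"1/564,000"`.
#' @export
format_one_in_n <- function(freq, sig_figs = 3) {
  stopifnot(length(freq) == 1)
  if (is.na(freq) || freq <= 0 || freq > 1) abort("freq must lie in (0, 1]")
  if (!sig_figs %in% 1:3) abort("sig_figs must be 1, 2 or 3")
  n <- 1 / freq
  n <- if (abs(n - round(n)) < 1e-9) round(n) else signif(n, sig_figs)
  paste0("1/", fmt_int(n))
}

#' Disease frequency in a clinically referred population
#'
#' @param n_cases Number of confirmed cases.
#' @param n_samples Total referred samples screened.
#' @return A string `"1 in N"`: N exact when `n_samples` is divisible by
#'   `n_cases`, otherwise rounded to 3 significant figures.
#' @export
#' @examples
#' clinically_referred_frequency(16, 22000) # "1 in 1,375"
clinically_referred_frequency <- function(n_cases, n_samples) {
  if (is.na(n_cases) || n_cases <= 0) abort("n_cases must be positive")
  if (is.na(n_samples) || n_samples < n_cases) {
    abort("n_samples must be at least n_cases")
  }
  n <- n_samples / n_cases
  n <- if (abs(n - round(n)) < 1e-9) round(n) else signif(n, 3)
  paste0("1 in ", fmt_int(n))
}

#' Per-population carrier and prevalence table across inclusion tiers
#'
#' Computes, for every population in a classified variant table, the
#' cumulative pathogenic allele frequency, Hardy-Weinberg carrier frequency
#' and disease prevalence for the base and extended tiers, and the
#' fold-increase in prevalence from extending the variant set (computed from
#' the unrounded prevalences).
#'
#' @inheritParams cumulative_frequencies
#' @param sig_figs Significant figures for the formatted strings (default 3).
#'
#' @return A tibble with one row per population: unrounded `q_base`,
#'   `carrier_base`, `prevalence_base`, `q_extended`, `carrier_extended`,
#'   `prevalence_extended`, `fold_increase`, and formatted
#'   `carrier_one_in_*` / `prevalence_one_in_*` columns.
#' @export
prevalence_table <- function(classified, population = NULL, sig_figs = 3) {
  cf <- cumulative_frequencies(classified, population = population)
  wide <- pivot_wider(cf, id_cols = "population", names_from = "tier",
                      values_from = "q")
  pmap(wide, function(population, base, base_plus_extended) {
    est_b <- hwe_estimates(base, sig_figs)
    est_e <- hwe_estimates(base_plus_extended, sig_figs)
    fold <- if (est_b$disease_prevalence > 0 && est_e$disease_prevalence > 0) {
      fold_increase(1 / est_b$disease_prevalence, 1 / est_e$disease_prevalence)
    } else {
      NA_real_
    }
    tibble(
      population = population,
      q_base = base,
      carrier_base = est_b$carrier_frequency,
      prevalence_base = est_b$disease_prevalence,
      q_extended = base_plus_extended,
      carrier_extended = est_e$carrier_frequency,
      prevalence_extended = est_e$disease_prevalence,
      fold_increase = fold,
      carrier_one_in_base = est_b$carrier_one_in,
      prevalence_one_in_base = est_b$prevalence_one_in,
      carrier_one_in_extended = est_e$carrier_one_in,
      prevalence_one_in_extended = est_e$prevalence_one_in
    )
  }) |> list_rbind()
}
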