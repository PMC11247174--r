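# Seeded synthetic-data generators.
#
# These emulate the two protected inputs of the analysis -- population
# variant tables with per-population AC/AN columns, and LC-MS intensity
# matrices with anchor specimens and a reference cohort -- and emit the
# planted parameters (SyntheticTruth) alongside every dataset so that
# downstream estimates can be checked against ground truth.

#' Configuration for the synthetic variant-table generator
#'
#' @param populations Named numeric vector of allele numbers (AN) per
#'   population label.
#' @param class_counts Named integer vector of variant counts per consequence
#'   class.
#' @param q_base Target cumulative allele frequency planted across the
#'   pathogenic/likely pathogenic (base-tier) variants. The default mirrors a
#'   pan-ethnic cumulative frequency of about 1.33e-3.
#' @param q_extended_extra Additional cumulative frequency planted across
#'   CADD-qualifying missense variants (the extended tier).
#' @param n_extended_missense Number of missense variants given CADD PHRED
#'   >= 28 and a share of `q_extended_extra`.
#' @param frac_reported Fraction of base-tier variants flagged as previously
#'   reported in an affected individual (classified pathogenic rather than
#'   likely pathogenic; the tier is unaffected).
#' @param mode Allele-count sampling: `"exact"` plants `AC = round(AF * AN)`
#'   (round-half-even) with no sampling noise; `"binomial"` draws
#'   `AC ~ Binomial(AN, AF)`.
#' @param include_excluded Add one benign-asserted common variant and one
#'   high-frequency variant so that the exclusion rules are exercised.
#' @return A config list for [simulate_variant_table()].
#' @export
variant_sim_config <- function(populations = c(pan_ethnic = 1e6),
                               class_counts = c(stop_gain = 3, frameshift = 2,
                                                canonical_splice = 2,
                                                start_loss = 1, missense = 6,
                                                synonymous = 3, stop_loss = 1),
                               q_base = 1.33156e-3,
                               q_extended_extra = 7.8e-4,
                               n_extended_missense = 3,
                               frac_reported = 0.4,
                               mode = c("exact", "binomial"),
                               include_excluded = TRUE) {
  stopifnot(length(populations) >= 1, !is.null(names(populations)),
            q_base >= 0, q_extended_extra >= 0,
            n_extended_missense <= class_counts[["missense"]])
  list(populations = populations, class_counts = class_counts,
       q_base = q_base, q_extended_extra = q_extended_extra,
       n_extended_missense = n_extended_missense,
       frac_reported = frac_reported, mode = match.arg(mode),
       include_excluded = include_excluded)
}

#' Simulate a population variant table with planted cumulative frequencies
#'
#' Generates a gnomAD-shaped variant table (one row per variant; per-population
#' `AC_<pop>`/`AN_<pop>` columns) whose truncating variants carry a planted
#' cumulative allele frequency `q_base` and whose CADD-qualifying missense
#' variants carry `q_extended_extra` on top. Deterministic given the seed.
#'
#' @param config A list from [variant_sim_config()].
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A list with `variants` (the table, ready for
#'   [classify_variants()]) and `truth`: a list with `seed`, `mode`, a `q`
#'   tibble (per population and tier: `q_target`, the planted `q` the
#'   estimator should recover, and `se`, the binomial standard error, 0 in
#'   exact mode) and the per-variant planted allele frequencies.
#' @export
simulate_variant_table <- function(config = variant_sim_config(), seed = 1) {
  with_seed(seed, {
    cc <- config$class_counts
    rows <- list()
    vid <- 0
    add_variant <- function(consequence, af, cadd = NA_real_,
                            spliceai = NA_real_, splice_offset = NA_real_,
                            reported = FALSE, benign = FALSE) {
      vid <<- vid + 1
      rows[[vid]] <<- tibble(
        variant_id = sprintf("var_%03d", vid),
        transcript = "NM_001080",
        hgvs_c = sprintf("c.%dG>A", 100 + vid * 7),
        hgvs_p = "",
        consequence = consequence,
        splice_offset = splice_offset,
        cadd_phred = cadd,
        spliceai_max = spliceai,
        reported_in_affected = reported,
        asserted_benign = benign,
        af = af
      )
    }

    # base tier: truncating classes share q_base
    base_classes <- c(rep("stop_gain", cc[["stop_gain"]]),
                      rep("frameshift", cc[["frameshift"]]),
                      rep("canonical_splice", cc[["canonical_splice"]]),
                      rep("start_loss", cc[["start_loss"]]))
    n_base <- length(base_classes)
    w <- runif(n_base)
    af_base <- w / sum(w) * config$q_base
    reported <- runif(n_base) < config$frac_reported
    for (i in seq_len(n_base)) {
      add_variant(base_classes[i], af_base[i],
                  splice_offset = if (base_classes[i] == "canonical_splice") {
                    sample(c(-2, -1, 1, 2), 1)
                  } else {
                    NA_real_
                  },
                  reported = reported[i])
    }

    # extended tier: missense with CADD >= 28 share q_extended_extra
    n_ext <- config$n_extended_missense
    if (n_ext > 0) {
      w <- runif(n_ext)
      af_ext <- w / sum(w) * config$q_extended_extra
      for (i in seq_len(n_ext)) {
        add_variant("missense", af_ext[i], cadd = runif(1, 28, 35))
      }
    }

    # remaining variants are excluded-tier VUS with trace frequencies
    for (i in seq_len(cc[["missense"]] - n_ext)) {
      add_variant("missense", 10^runif(1, -6.5, -5.5), cadd = runif(1, 15, 27.5))
    }
    for (i in seq_len(cc[["synonymous"]])) {
      add_variant("synonymous", 10^runif(1, -6, -4.5))
    }
    for (i in seq_len(cc[["stop_loss"]])) {
      add_variant("stop_loss", 10^runif(1, -6.5, -5.5))
    }
    if (config$include_excluded) {
      add_variant("synonymous", 0.02, benign = TRUE)
      add_variant("missense", 0.05, cadd = runif(1, 20, 27))
    }

    variants <- list_rbind(rows)
    af <- variants$af
    variants$af <- NULL

    pops <- config$populations
    qualifying <- seq_len(n_base + n_ext)
    for (p in names(pops)) {
      an <- pops[[p]]
      if (config$mode == "exact") {
        low <- af > 0 & af * an < 1
        if (any(low[qualifying])) {
          warn(sprintf(
            "%d qualifying variant(s) with AF * AN < 1 drop to AC = 0 in %s",
            sum(low[qualifying]), p
          ))
        }
        ac <- ifelse(low, 0, round(af * an))
      } else {
        ac <- rbinom(length(af), size = an, prob = af)
      }
      variants[[paste0("AC_", p)]] <- as.integer(ac)
      variants[[paste0("AN_", p)]] <- as.integer(rep(an, length(af)))
    }

    base_idx <- seq_len(n_base)
    ext_idx <- if (n_ext > 0) n_base + seq_len(n_ext) else integer()
    truth_q <- map(names(pops), function(p) {
      an <- pops[[p]]
      ac <- variants[[paste0("AC_", p)]]
      planted <- function(idx) {
        if (config$mode == "exact") {
          list(q = sum(ac[idx]) / an, se = 0)
        } else {
          list(q = sum(af[idx]),
               se = sqrt(sum(af[idx] * (1 - af[idx]) / an)))
        }
      }
      b <- planted(base_idx)
      e <- planted(c(base_idx, ext_idx))
      tibble(
        population = p,
        tier = c("base", "base_plus_extended"),
        q_target = c(config$q_base, config$q_base + config$q_extended_extra),
        q = c(b$q, e$q),
        se = c(b$se, e$se)
      )
    }) |> list_rbind()

    list(
      variants = variants,
      truth = list(seed = seed, mode = config$mode, q = truth_q,
                   af = tibble(variant_id = variants$variant_id, af = af))
    )
  })
}

#' Configuration for the synthetic metabolomics generator
#'
#' Intensities are log-normal per metabolite; case samples carry planted
#' z-shifts on the disease markers (log-value = mean_log + z_target * sd_log,
#' z_target drawn uniformly within the group's range); decoy metabolites have
#' no planted shift; every sample is multiplied by its batch's factor, which
#' the anchor specimens absorb.
#'
#' @param n_reference Reference cohort size (default 395).
#' @param n_batches,n_anchors_per_batch Batch structure; anchors are
#'   invariant specimens (planted at the metabolite location).
#' @param specimen `"plasma"` or `"urine"`; selects the default case groups
#'   and, for urine, per-sample creatinine.
#' @param n_decoys Number of unshifted decoy metabolites alongside the five
#'   pathway markers.
#' @param case_groups Named list of groups, each `list(n =, age_range =,
#'   shifts = list(metabolite = c(lo, hi)))`. Defaults: plasma -- pediatric
#'   SSADHD (n = 8; 2-pyrrolidinone z in [3.12, 6.50], 4-guanidinobutanoate
#'   in [2.61, 4.03]), adult SSADHD (n = 5; [0.02, 1.24] and [1.70, 2.38]),
#'   GABA-TD (n = 5; 2-pyrrolidinone and succinamic acid in [3, 6]); urine --
#'   pediatric SSADHD (succinimide [2.09, 3.16], 4-guanidinobutanoate
#'   [1.91, 2.78]) and adult SSADHD (succinimide [1.02, 1.72]).
#' @param batch_sd SD of the log-normal batch factors.
#' @param missing_rate Uniform missingness rate applied to non-anchor
#'   samples.
#' @return A config list for [simulate_metabolomics()].
#' @export
metabo_sim_config <- function(n_reference = 395, n_batches = 4,
                              n_anchors_per_batch = 3,
                              specimen = c("plasma", "urine"),
                              n_decoys = 10, case_groups = NULL,
                              batch_sd = 0.5, missing_rate = 0) {
  specimen <- match.arg(specimen)
  if (is.null(case_groups)) {
    case_groups <- if (specimen == "plasma") {
      list(
        ssadhd_pediatric = list(
          n = 8, age_range = c(0.5, 12),
          shifts = setNames(
            list(c(3.12, 6.50), c(2.61, 4.03)),
            c(marker_pyrrolidinone, marker_guanidinobutanoate)
          )
        ),
        ssadhd_adult = list(
          n = 5, age_range = c(22, 44),
          shifts = setNames(
            list(c(0.02, 1.24), c(1.70, 2.38)),
            c(marker_pyrrolidinone, marker_guanidinobutanoate)
          )
        ),
        gabat = list(
          n = 5, age_range = c(0.5, 12),
          shifts = setNames(
            list(c(3, 6), c(2.5, 5)),
            c(marker_pyrrolidinone, marker_succinamic)
          )
        )
      )
    } else {
      list(
        ssadhd_pediatric = list(
          n = 7, age_range = c(0.5, 12),
          shifts = setNames(
            list(c(2.09, 3.16), c(1.91, 2.78)),
            c(marker_succinimide, marker_guanidinobutanoate)
          )
        ),
        ssadhd_adult = list(
          n = 5, age_range = c(22, 44),
          shifts = setNames(
            list(c(1.02, 1.72), c(1.91, 2.78)),
            c(marker_succinimide, marker_guanidinobutanoate)
          )
        )
      )
    }
  }
  panel <- c(gaba_markers(),
             if (n_decoys > 0) sprintf("decoy_%02d", seq_len(n_decoys)))
  for (g in names(case_groups)) {
    missing <- setdiff(names(case_groups[[g]]$shifts), panel)
    if (length(missing) > 0) {
      abort(sprintf("case group '%s' shifts metabolite(s) absent from the panel: %s",
                    g, paste(missing, collapse = ", ")))
    }
  }
  list(n_reference = n_reference, n_batches = n_batches,
       n_anchors_per_batch = n_anchors_per_batch, specimen = specimen,
       panel = panel, case_groups = case_groups, batch_sd = batch_sd,
       missing_rate = missing_rate)
}

#' Simulate an LC-MS-like intensity matrix with planted disease signatures
#'
#' @param config A list from [metabo_sim_config()].
#' @param seed Integer seed; identical seeds give identical data.
#' @return A list with `intensities` (wide tibble, `sample_id` + metabolite
#'   columns), `samples` (sample sheet: `sample_id`, `specimen`, `batch`,
#'   `is_anchor`, `is_reference`, `group`, `age_years`, `sex`, `creatinine`)
#'   and `truth`: `z_targets` (per planted sample x marker), per-metabolite
#'   `params` (`mean_log`, `sd_log`), `batch_factors` and `seed`.
#' @export
simulate_metabolomics <- function(config = metabo_sim_config(), seed = 1) {
  with_seed(seed, {
    panel <- config$panel
    n_met <- length(panel)
    params <- tibble(
      metabolite = panel,
      mean_log = runif(n_met, 2, 8),
      sd_log = runif(n_met, 0.2, 0.6)
    )
    batches <- sprintf("batch_%d", seq_len(config$n_batches))
    batch_factor <- setNames(exp(rnorm(config$n_batches, 0, config$batch_sd)),
                             batches)

    sheet <- list()
    values <- list()
    targets <- list()
    add_sample <- function(id, batch, is_anchor, is_reference, group,
                           age, z_by_met) {
      sheet[[length(sheet) + 1]] <<- tibble(
        sample_id = id, specimen = config$specimen, batch = batch,
        is_anchor = is_anchor, is_reference = is_reference, group = group,
        age_years = age, sex = sample(c("M", "F"), 1),
        creatinine = if (config$specimen == "urine" && !is_anchor) {
          round(runif(1, 2, 20), 2)
        } else {
          1
        }
      )
      values[[length(values) + 1]] <<- z_by_met
    }

    for (b in batches) {
      for (k in seq_len(config$n_anchors_per_batch)) {
        add_sample(sprintf("anchor_%s_%d", b, k), b, TRUE, FALSE, "anchor",
                   NA_real_, rep(0, n_met))
      }
    }
    ref_batches <- rep(batches, length.out = config$n_reference)
    for (i in seq_len(config$n_reference)) {
      add_sample(sprintf("ref_%04d", i), ref_batches[i], FALSE, TRUE,
                 "reference", round(runif(1, 0.5, 17), 1), rnorm(n_met))
    }
    for (g in names(config$case_groups)) {
      grp <- config$case_groups[[g]]
      for (i in seq_len(grp$n)) {
        id <- sprintf("%s_%02d", g, i)
        z <- rnorm(n_met)
        for (m in names(grp$shifts)) {
          zt <- runif(1, grp$shifts[[m]][1], grp$shifts[[m]][2])
          z[match(m, panel)] <- zt
          targets[[length(targets) + 1]] <- tibble(
            sample_id = id, group = g, metabolite = m, z_target = zt
          )
        }
        add_sample(id, sample(batches, 1), FALSE, FALSE, g,
                   round(runif(1, grp$age_range[1], grp$age_range[2]), 1), z)
      }
    }

    samples <- list_rbind(sheet)
    zmat <- do.call(rbind, values)
    vmat <- exp(sweep(sweep(zmat, 2, params$sd_log, `*`),
                      2, params$mean_log, `+`))
    vmat <- vmat * batch_factor[samples$batch] * samples$creatinine

    if (config$missing_rate > 0) {
      mask <- matrix(runif(length(vmat)) < config$missing_rate,
                     nrow = nrow(vmat))
      mask[samples$is_anchor, ] <- FALSE
      vmat[mask] <- NA_real_
    }

    intensities <- as_tibble(as.data.frame(vmat, check.names = FALSE))
    names(intensities) <- panel
    intensities <- bind_cols(tibble(sample_id = samples$sample_id),
                             intensities)

    list(
      intensities = intensities,
      samples = samples,
      truth = list(
        seed = seed,
        z_targets = if (length(targets)) list_rbind(targets) else tibble(),
        params = params,
        batch_factors = batch_factor
      )
    )
  })
}

#' Simulate a diagnostic cohort table
#'
#' Generates a cohort table shaped like a clinical case series: ages drawn
#' under pediatric/adult quotas (default 18 pediatric of 24), biallelic
#' genotypes sampled from an allele pool, and urine GHB drawn above the
#' normal range for cases and inside it (0-7 mmol/mol creatinine) for
#' controls.
#'
#' @param n Cohort size (default 24).
#' @param seed Integer seed.
#' @param n_pediatric Exact number of pediatric (age <= 18) subjects; the
#'   default keeps the 18:6 pediatric:adult ratio of the published series.
#' @param allele_pool Character vector of cDNA HGVS alleles to sample
#'   genotypes from.
#' @param status `"case"` or `"control"` per subject (recycled; default all
#'   cases).
#' @return A tibble with columns `subject_id`, `age_years`, `sex`,
#'   `clinical_flags`, `urine_ghb`, `ghb_reported_abnormal`,
#'   `imaging_suggestive`, `allele1`, `allele2`, `class1`, `class2`,
#'   `status`.
#' @export
simulate_cohort <- function(n = 24, seed = 1, n_pediatric = round(n * 18 / 24),
                            allele_pool = c("c.612G>A", "c.1015-2A>C",
                                            "c.1597G>A", "c.1234C>T",
                                            "c.803G>A", "c.608C>T",
                                            "c.668G>A", "c.379_380del"),
                            status = "case") {
  if (n <= 0) abort("n must be positive")
  if (n_pediatric > n) abort("n_pediatric cannot exceed n")
  stopifnot(length(allele_pool) >= 1)
  with_seed(seed, {
    status <- rep(status, length.out = n)
    ages <- c(round(runif(n_pediatric, 0.5, 12) * 2) / 2,
              round(runif(n - n_pediatric, 22, 44)))
    is_case <- status == "case"
    ghb <- ifelse(is_case,
                  round(10^runif(n, log10(50), log10(5000)), 1),
                  round(runif(n, 0, 7), 1))
    flags <- vapply(seq_len(n), function(i) {
      if (is_case[i]) {
        paste(sample(suspicion_flags(), sample(1:3, 1)), collapse = ";")
      } else {
        ""
      }
    }, character(1))
    a1 <- sample(allele_pool, n, replace = TRUE)
    a2 <- ifelse(runif(n) < 0.3, a1, sample(allele_pool, n, replace = TRUE))
    tibble(
      subject_id = sprintf("subj_%02d", seq_len(n)),
      age_years = ages,
      sex = sample(c("M", "F"), n, replace = TRUE),
      clinical_flags = flags,
      urine_ghb = ghb,
      ghb_reported_abnormal = NA,
      imaging_suggestive = NA,
      allele1 = ifelse(is_case, a1, NA_character_),
      allele2 = ifelse(is_case, a2, NA_character_),
      class1 = ifelse(is_case, "pathogenic", NA_character_),
      class2 = ifelse(is_case, "likely_pathogenic", NA_character_),
      status = status
    )
  })
}
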