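subject <- function(id = "s1", ...) {
  defaults <- list(
    subject_id = id, age_years = 5, sex = "F",
    clinical_flags = NA_character_, urine_ghb = NA_real_,
    ghb_reported_abnormal = NA, imaging_suggestive = NA,
    allele1 = NA_character_, allele2 = NA_character_,
    class1 = NA_character_, class2 = NA_character_
  )
  args <- list(...)
  defaults[names(args)] <- args
  tibble::as_tibble(defaults)
}

test_that("zygosity is string equality of detected alleles", {
  expect_equal(zygosity("c.668G>A", "c.668G>A"), "homozygous")
  expect_equal(zygosity("c.1597G>A", "c.1015-2A>C"), "compound_heterozygous")
  expect_equal(zygosity("c.612G>A", NA), "single_heterozygous")
  expect_equal(zygosity(NA, ""), "none")
  expect_equal(zygosity(" c.612G>A ", "c.612G>A"), "homozygous")
})

test_that("the integrated diagnosis grades evidence channels", {
  subj <- dplyr::bind_rows(
    subject("both", allele1 = "c.1597G>A", allele2 = "c.1015-2A>C",
            class1 = "pathogenic", class2 = "pathogenic",
            ghb_reported_abnormal = TRUE,
            clinical_flags = "developmental_delay;hypotonia"),
    subject("mol_only", allele1 = "c.612G>A", allele2 = "c.1234C>T",
            class1 = "pathogenic", class2 = "likely_pathogenic"),
    subject("bio_only", urine_ghb = 431.4),
    subject("clinical_only", clinical_flags = "developmental_delay"),
    subject("nothing", urine_ghb = 3,
            clinical_flags = "unrelated_flag")
  )
  out <- integrated_diagnosis(subj)
  got <- setNames(out$diagnosis, out$subject_id)
  expect_equal(got[["both"]], "comprehensively_confirmed")
  expect_equal(got[["mol_only"]], "molecularly_confirmed")
  expect_equal(got[["bio_only"]], "biochemically_supported")
  expect_equal(got[["clinical_only"]], "suspected")
  expect_equal(got[["nothing"]], "not_supported")

  # one VUS allele does not satisfy the molecular criterion
  vus <- integrated_diagnosis(subject("v", allele1 = "c.1G>A",
                                      allele2 = "c.2G>A",
                                      class1 = "pathogenic", class2 = "vus"))
  expect_equal(vus$diagnosis, "not_supported")

  # a positive plasma signature satisfies the biochemical criterion
  sig <- tibble::tibble(sample_id = "m", call = "positive")
  with_sig <- integrated_diagnosis(subject("m", clinical_flags = "hypotonia"),
                                   signatures = sig)
  expect_equal(with_sig$diagnosis, "biochemically_supported")

  expect_error(integrated_diagnosis(subject("empty")), "no evidence")
})

test_that("adding evidence never downgrades the diagnosis", {
  order <- c(not_supported = 1, suspected = 2, biochemically_supported = 3,
             molecularly_confirmed = 3, comprehensively_confirmed = 4)
  base <- subject("s", urine_ghb = 3, clinical_flags = "unrelated")
  upgrades <- list(
    function(s) dplyr::mutate(s, clinical_flags = "seizures"),
    function(s) dplyr::mutate(s, urine_ghb = 500),
    function(s) dplyr::mutate(s, allele1 = "c.612G>A", allele2 = "c.612G>A",
                              class1 = "pathogenic", class2 = "pathogenic"),
    function(s) dplyr::mutate(s, imaging_suggestive = TRUE)
  )
  # apply every subset of upgrades; more evidence must never rank lower
  for (k in seq_along(upgrades)) {
    combos <- utils::combn(seq_along(upgrades), k, simplify = FALSE)
    for (cmb in combos) {
      s <- base
      for (i in cmb) s <- upgrades[[i]](s)
      with_more <- integrated_diagnosis(s)$diagnosis
      # dropping any one channel from the combo cannot rank higher
      for (i in cmb) {
        s_less <- base
        for (j in setdiff(cmb, i)) s_less <- upgrades[[j]](s_less)
        with_less <- integrated_diagnosis(s_less)$diagnosis
        expect_lte(order[[with_less]], order[[with_more]])
      }
    }
  }
})

test_that("cohort summaries are exact and permutation-invariant", {
  one <- cohort_summary(subject("solo", age_years = 5, sex = "M"))
  expect_equal(one$mean_age, 5)
  expect_equal(one$median_age, 5)
  expect_equal(one$n_male, 1)
  expect_true(is.na(one$sd_age))

  coh <- ssadhd_cohort()
  s1 <- cohort_summary(coh)
  perm <- withr::with_seed(3, sample.int(nrow(coh)))
  s2 <- cohort_summary(coh[perm, ])
  expect_equal(s1, s2)

  # five Table-style homozygote rows among the first 16 subjects
  expect_equal(cohort_summary(coh[1:16, ])$n_homozygous, 5)
  expect_error(cohort_summary(coh[0, ]), "empty")
})
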