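test_that("classification follows the evidence rules and their precedence", {
  tbl <- make_variants(
    list(variant_id = "stopgain_reported", consequence = "stop_gain",
         reported_in_affected = TRUE),
    list(variant_id = "frameshift_unreported", consequence = "frameshift"),
    list(variant_id = "stoploss_bare", consequence = "stop_loss"),
    list(variant_id = "stoploss_reported", consequence = "stop_loss",
         reported_in_affected = TRUE),
    list(variant_id = "splice_minus2", consequence = "canonical_splice",
         splice_offset = -2),
    list(variant_id = "splice_plus5", consequence = "canonical_splice",
         splice_offset = 5),
    list(variant_id = "common_synonymous", consequence = "synonymous",
         AC_pan_ethnic = 300000L),
    list(variant_id = "benign_and_common", consequence = "missense",
         asserted_benign = TRUE, AC_pan_ethnic = 300000L),
    list(variant_id = "reported_but_common", consequence = "missense",
         reported_in_affected = TRUE, AC_pan_ethnic = 300000L)
  )
  out <- classify_variants(tbl)
  got <- setNames(out$classification, out$variant_id)
  expect_equal(got[["stopgain_reported"]], "pathogenic")
  expect_equal(got[["frameshift_unreported"]], "likely_pathogenic")
  expect_equal(got[["stoploss_bare"]], "vus")
  expect_equal(got[["stoploss_reported"]], "vus")
  expect_equal(got[["splice_minus2"]], "likely_pathogenic")
  expect_equal(got[["splice_plus5"]], "vus")
  expect_equal(got[["common_synonymous"]], "excluded_frequency")
  # benign assertion outranks frequency; both outrank evidence of pathogenicity
  expect_equal(got[["benign_and_common"]], "excluded_benign")
  expect_equal(got[["reported_but_common"]], "excluded_frequency")
  # stop-loss never reaches P/LP
  expect_false(any(out$classification[out$consequence == "stop_loss"] %in%
                     c("pathogenic", "likely_pathogenic")))
})

test_that("canonical splice variants need a splice offset", {
  tbl <- make_variants(
    list(variant_id = "bad_splice", consequence = "canonical_splice")
  )
  expect_error(classify_variants(tbl), "splice_offset")
  expect_error(classify_variants(tbl), "bad_splice")
})

test_that("tier cutoffs are inclusive and exclusions never enter a tier", {
  tbl <- make_variants(
    list(variant_id = "cadd_at_cutoff", consequence = "missense",
         cadd_phred = 28.0),
    list(variant_id = "cadd_below", consequence = "missense",
         cadd_phred = 25.7),
    list(variant_id = "sai_at_cutoff", consequence = "other",
         spliceai_max = 0.2),
    list(variant_id = "sai_below", consequence = "synonymous",
         spliceai_max = 0.19),
    list(variant_id = "plp_no_scores", consequence = "stop_gain"),
    list(variant_id = "inframe_high_cadd", consequence = "inframe_indel",
         cadd_phred = 35),
    list(variant_id = "common_high_cadd", consequence = "missense",
         cadd_phred = 35, AC_pan_ethnic = 300000L)
  )
  out <- classify_variants(tbl)
  got <- setNames(out$inclusion_tier, out$variant_id)
  expect_equal(got[["cadd_at_cutoff"]], "extended_only")
  expect_equal(got[["cadd_below"]], "excluded")
  expect_equal(got[["sai_at_cutoff"]], "extended_only")
  expect_equal(got[["sai_below"]], "excluded")
  expect_equal(got[["plp_no_scores"]], "base")
  # the CADD branch is missense-only
  expect_equal(got[["inframe_high_cadd"]], "excluded")
  # frequency-excluded variants never qualify, whatever their scores
  expect_equal(got[["common_high_cadd"]], "excluded")
})

test_that("classification matches a brute-force oracle and ignores row order", {
  for (seed in c(11, 23, 47)) {
    tbl <- random_variant_table(n = 20, seed = seed)
    out <- classify_variants(tbl)
    for (i in seq_len(nrow(tbl))) {
      v <- as.list(tbl[i, ])
      cls <- oracle_classify_one(v)
      expect_equal(out$classification[i], cls, label = sprintf(
        "classification seed %d row %d", seed, i
      ))
      expect_equal(out$inclusion_tier[i], oracle_tier_one(v, cls),
                   label = sprintf("tier seed %d row %d", seed, i))
    }
    # order-independence: shuffling rows shuffles results identically
    perm <- withr::with_seed(seed + 1, sample.int(nrow(tbl)))
    out_perm <- classify_variants(tbl[perm, ])
    expect_equal(out_perm$classification, out$classification[perm])
    expect_equal(out_perm$inclusion_tier, out$inclusion_tier[perm])
    # tier monotonicity: extended set contains the base set
    base_set <- out$variant_id[out$inclusion_tier == "base"]
    ext_set <- out$variant_id[out$inclusion_tier %in% c("base", "extended_only")]
    expect_true(all(base_set %in% ext_set))
  }
})

test_that("variant tables are validated on read with row-numbered messages", {
  good <- make_variants(
    list(variant_id = "a", consequence = "stop_gain"),
    list(variant_id = "b", consequence = "missense", cadd_phred = 30),
    list(variant_id = "c", consequence = "synonymous")
  )
  path <- write_variant_tsv(good)
  rec <- read_variant_table(path)
  expect_equal(nrow(rec), 3)
  expect_type(rec$cadd_phred, "double")
  expect_type(rec$reported_in_affected, "logical")

  bad_ac <- good
  bad_ac$AC_pan_ethnic[2] <- 2000000L
  expect_error(read_variant_table(write_variant_tsv(bad_ac)),
               "row 2.*AC_pan_ethnic.*exceeds")

  dup <- good
  dup$variant_id[3] <- "a"
  expect_error(read_variant_table(write_variant_tsv(dup)), "duplicate")

  malformed <- good
  malformed$cadd_phred <- as.character(malformed$cadd_phred)
  malformed$cadd_phred[1] <- "high"
  expect_error(read_variant_table(write_variant_tsv(malformed)),
               "row 1.*malformed numeric")

  empty <- good[0, ]
  rec0 <- read_variant_table(write_variant_tsv(empty))
  expect_equal(nrow(rec0), 0)

  missing_col <- good
  missing_col$consequence <- NULL
  expect_error(read_variant_table(write_variant_tsv(missing_col)),
               "consequence")
})

test_that("allele identity is the cDNA string; fractions truncate", {
  coh <- ssadhd_cohort()
  bgbcm <- coh[coh$cohort == "BG-BCM", ]
  alleles <- c(bgbcm$allele1, bgbcm$allele2)
  expect_equal(unique_variant_count(alleles), 19)
  known <- setdiff(alleles, ssadhd_novel_variants())
  expect_equal(novel_fraction(alleles, known), 15.7)

  expect_equal(unique_variant_count(rep("c.612G>A", 4)), 1)
  # whitespace is not identity; protein-level differences are invisible here
  expect_equal(unique_variant_count(c("c.1323dup", " c.1323dup ")), 1)
  # truncation, not rounding: 1/6 of distinct alleles -> 16.6, not 16.7
  expect_equal(novel_fraction(sprintf("c.%dG>A", 1:6), sprintf("c.%dG>A", 1:5)),
               16.6)
  expect_error(unique_variant_count(c(NA, "")), "non-missing")
})
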