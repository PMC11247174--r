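simple_batch <- function(values) {
  # one batch, two anchors (rows a1, a2) + samples from a named value matrix
  samples <- tibble::tibble(
    sample_id = rownames(values),
    batch = "b1",
    is_anchor = rownames(values) %in% c("a1", "a2"),
    is_reference = !rownames(values) %in% c("a1", "a2")
  )
  list(intensities = make_matrix(values, samples), samples = samples)
}

test_that("creatinine normalization divides per sample and cancels downstream", {
  vals <- matrix(c(100, 80, 60), ncol = 1,
                 dimnames = list(c("s1", "s2", "s3"), "m1"))
  m <- make_matrix(vals, NULL)
  samples <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                            creatinine = c(2, 1, 4))
  out <- creatinine_normalize(m, samples)
  expect_equal(out$m1, c(50, 80, 15))

  samples$creatinine[2] <- 0
  expect_error(creatinine_normalize(m, samples), "positive")

  # a common creatinine factor leaves z-scores untouched when the reference
  # is built from the same normalized data
  sim <- simulate_metabolomics(metabo_sim_config(n_reference = 40,
                                                 n_decoys = 2), seed = 3)
  base <- metabolite_zscores(
    anchor_normalize(sim$intensities, sim$samples),
    build_reference(anchor_normalize(sim$intensities, sim$samples),
                    sim$samples)
  )
  scaled <- sim$intensities
  for (m2 in setdiff(names(scaled), "sample_id")) {
    scaled[[m2]] <- scaled[[m2]] * 3
  }
  sheet <- dplyr::mutate(sim$samples, creatinine = 3)
  normed <- creatinine_normalize(scaled, sheet)
  redo <- metabolite_zscores(anchor_normalize(normed, sheet),
                             build_reference(anchor_normalize(normed, sheet),
                                             sheet))
  expect_equal(redo$z, base$z, tolerance = 1e-12)
})

test_that("anchor normalization uses the batch anchor median", {
  vals <- matrix(c(2, 4, 6), ncol = 1,
                 dimnames = list(c("a1", "a2", "s1"), "m1"))
  fx <- simple_batch(vals)
  out <- anchor_normalize(fx$intensities, fx$samples)
  expect_equal(out$m1, c(2 / 3, 4 / 3, 2)) # anchors {2,4}: median 3

  # anchors all equal to the sample give exactly 1
  vals2 <- matrix(c(5, 5, 5), ncol = 1,
                  dimnames = list(c("a1", "a2", "s1"), "m1"))
  fx2 <- simple_batch(vals2)
  expect_equal(anchor_normalize(fx2$intensities, fx2$samples)$m1, c(1, 1, 1))

  # a batch without anchors is an error; missing anchor coverage warns
  no_anchor <- fx$samples
  no_anchor$is_anchor <- FALSE
  expect_error(anchor_normalize(fx$intensities, no_anchor), "anchor")

  vals3 <- vals
  vals3[c("a1", "a2"), "m1"] <- NA_real_
  fx3 <- simple_batch(vals3)
  expect_warning(out3 <- anchor_normalize(fx3$intensities, fx3$samples),
                 "coverage")
  expect_true(all(is.na(out3$m1)))
})

test_that("batch-wide scale factors cancel through the full pipeline", {
  sim <- simulate_metabolomics(metabo_sim_config(n_reference = 60,
                                                 n_decoys = 3), seed = 11)
  run <- function(intensities) {
    norm <- anchor_normalize(intensities, sim$samples)
    metabolite_zscores(norm, build_reference(norm, sim$samples), sim$samples)
  }
  base <- run(sim$intensities)
  scaled <- sim$intensities
  in_b1 <- sim$samples$batch[match(scaled$sample_id,
                                   sim$samples$sample_id)] == "batch_1"
  for (m in setdiff(names(scaled), "sample_id")) {
    scaled[[m]][in_b1] <- scaled[[m]][in_b1] * 10
  }
  expect_equal(run(scaled)$z, base$z, tolerance = 1e-10)
})

test_that("reference statistics are the log-scale mean and sample SD", {
  vals <- matrix(exp(c(0, 2, 1, 1)), ncol = 2,
                 dimnames = list(c("r1", "r2"), c("m1", "m_const")))
  m <- make_matrix(vals, NULL)
  expect_warning(ref <- build_reference(m), "constant")
  expect_equal(ref$mean_log[ref$metabolite == "m1"], 1)
  expect_equal(ref$sd_log[ref$metabolite == "m1"], sqrt(2))
  expect_false("m_const" %in% ref$metabolite)
  expect_equal(attr(ref, "n_reference"), 2)

  # planted log-normal cohort recovered within 3 standard errors
  n <- 300
  mu <- 1.4
  sigma <- 0.5
  vals2 <- withr::with_seed(21, matrix(exp(rnorm(n, mu, sigma)), ncol = 1,
                                       dimnames = list(sprintf("r%03d", 1:n),
                                                       "m1")))
  ref2 <- build_reference(make_matrix(vals2, NULL))
  expect_lt(abs(ref2$mean_log - mu), 3 * sigma / sqrt(n))
  expect_lt(abs(ref2$sd_log - sigma), 3 * sigma / sqrt(2 * (n - 1)))

  expect_error(build_reference(make_matrix(vals2[1, , drop = FALSE], NULL)),
               ">= 2")
})

test_that("z-scores and abnormality flags follow the inclusive 2-SD rule", {
  ref <- tibble::tibble(metabolite = "m1", mean_log = 1, sd_log = 0.5)
  m <- make_matrix(matrix(exp(c(1, 2, -0.001, NA, 1.25)), ncol = 1,
                          dimnames = list(sprintf("s%d", 1:5), "m1")), NULL)
  m$m1[3] <- -4 # non-positive raw value
  expect_warning(z <- metabolite_zscores(m, ref), "non-positive")
  expect_equal(z$z[1], 0)
  expect_equal(z$flag[1], "normal")
  expect_equal(z$z[2], 2) # exactly mean + 2 SD
  expect_equal(z$flag[2], "high")
  expect_equal(z$flag[3], "not_reported")
  expect_equal(z$flag[4], "not_reported")
  expect_equal(z$flag[5], "normal")

  low <- make_matrix(matrix(exp(0), ncol = 1,
                            dimnames = list("s1", "m1")), NULL)
  expect_equal(metabolite_zscores(low, ref)$flag, "low") # z = -2 inclusive

  # no profile can be both high and low, across random data
  sim <- simulate_metabolomics(metabo_sim_config(n_reference = 50,
                                                 n_decoys = 2), seed = 13)
  norm <- anchor_normalize(sim$intensities, sim$samples)
  zz <- metabolite_zscores(norm, build_reference(norm, sim$samples))
  expect_true(all(zz$flag %in% c("high", "low", "normal", "not_reported")))
  expect_true(all((zz$z >= 2) == (zz$flag == "high"), na.rm = TRUE))
  expect_true(all((zz$z <= -2) == (zz$flag == "low"), na.rm = TRUE))
})

test_that("the reference cohort scores against itself as standard normal", {
  sim <- simulate_metabolomics(metabo_sim_config(), seed = 17)
  norm <- anchor_normalize(sim$intensities, sim$samples)
  ref <- build_reference(norm, sim$samples)
  z <- metabolite_zscores(norm, ref, sim$samples)
  self <- dplyr::filter(z, .data$group == "reference")
  by_met <- dplyr::summarise(dplyr::group_by(self, .data$metabolite),
                             m = mean(z), s = sd(z))
  expect_true(all(abs(by_met$m) < 0.05))
  expect_true(all(by_met$s > 0.95 & by_met$s < 1.05))
})
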