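# Builders for small in-code fixtures, plus an independent brute-force
# re-implementation of the classification rule text used as an oracle.

make_variants <- function(...) {
  rows <- list(...)
  purrr::map(rows, function(r) {
    defaults <- list(
      variant_id = NA_character_, transcript = "NM_001080",
      hgvs_c = NA_character_, hgvs_p = "",
      consequence = "missense", splice_offset = NA_real_,
      cadd_phred = NA_real_, spliceai_max = NA_real_,
      reported_in_affected = FALSE, asserted_benign = FALSE,
      AC_pan_ethnic = 5L, AN_pan_ethnic = 1000000L
    )
    defaults[names(r)] <- r
    tibble::as_tibble(defaults)
  }) |> purrr::list_rbind() |>
    dplyr::mutate(variant_id = dplyr::coalesce(
      variant_id, sprintf("v%02d", dplyr::row_number())
    ))
}

random_variant_table <- function(n, seed) {
  withr::with_seed(seed, {
    csq <- sample(c("stop_gain", "frameshift", "canonical_splice",
                    "start_loss", "stop_loss", "missense", "synonymous",
                    "inframe_indel", "other"), n, replace = TRUE)
    tibble::tibble(
      variant_id = sprintf("r%03d", seq_len(n)),
      transcript = "NM_001080",
      hgvs_c = sprintf("c.%dA>G", seq_len(n) * 3),
      hgvs_p = "",
      consequence = csq,
      splice_offset = ifelse(csq == "canonical_splice",
                             sample(c(-3, -2, -1, 1, 2, 3), n, replace = TRUE),
                             NA_real_),
      cadd_phred = ifelse(runif(n) < 0.7, runif(n, 10, 40), NA_real_),
      spliceai_max = ifelse(runif(n) < 0.5, runif(n), NA_real_),
      reported_in_affected = runif(n) < 0.3,
      asserted_benign = runif(n) < 0.1,
      AC_pan_ethnic = as.integer(rbinom(n, 40000, 0.001)),
      AN_pan_ethnic = 1000000L,
      AC_african = as.integer(rbinom(n, 4000, 0.001)),
      AN_african = 60000L
    )
  })
}

# literal, case-by-case restatement of the published inclusion criteria --
# deliberately written as nested conditionals, independent of the vectorized
# implementation
oracle_classify_one <- function(v, max_credible_af = 0.01) {
  if (isTRUE(v$asserted_benign)) {
    return("excluded_benign")
  }
  for (p in c("pan_ethnic", "african")) {
    ac <- v[[paste0("AC_", p)]]
    an <- v[[paste0("AN_", p)]]
    if (!is.null(ac) && !is.na(ac) && !is.na(an) && ac / an > max_credible_af) {
      return("excluded_frequency")
    }
  }
  if (isTRUE(v$reported_in_affected) && v$consequence != "stop_loss") {
    return("pathogenic")
  }
  if (v$consequence == "stop_gain") return("likely_pathogenic")
  if (v$consequence == "frameshift") return("likely_pathogenic")
  if (v$consequence == "start_loss") return("likely_pathogenic")
  if (v$consequence == "canonical_splice") {
    if (abs(v$splice_offset) == 1 || abs(v$splice_offset) == 2) {
      return("likely_pathogenic")
    }
  }
  "vus"
}

oracle_tier_one <- function(v, cls, cadd_cutoff = 28, spliceai_cutoff = 0.2) {
  if (cls == "pathogenic" || cls == "likely_pathogenic") {
    return("base")
  }
  if (cls != "vus") {
    return("excluded")
  }
  if (v$consequence == "missense" && !is.na(v$cadd_phred) &&
      v$cadd_phred >= cadd_cutoff) {
    return("extended_only")
  }
  if (!is.na(v$spliceai_max) && v$spliceai_max >= spliceai_cutoff) {
    return("extended_only")
  }
  "excluded"
}

# wide intensity matrix + sample sheet from explicit values
make_matrix <- function(values, samples) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  tibble::as_tibble(as.data.frame(values, check.names = FALSE)) |>
    dplyr::mutate(sample_id = rownames(values), .before = 1)
}

# long z-score table for one sample from named z values
make_ztbl <- function(sample_id, specimen, z) {
  tibble::tibble(
    sample_id = sample_id,
    specimen = specimen,
    metabolite = names(z),
    z = unname(z),
    flag = dplyr::case_when(
      is.na(z) ~ "not_reported",
      z >= 2 ~ "high",
      z <= -2 ~ "low",
      .default = "normal"
    )
  )
}

write_variant_tsv <- function(df, path = withr::local_tempfile(fileext = ".tsv",
                                                               .local_envir = parent.frame())) {
  readr::write_tsv(df, path, na = "")
  path
}
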