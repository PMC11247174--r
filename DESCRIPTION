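Package: gabadx
Title: Integrated Molecular and Metabolomic Diagnostics for GABA Catabolism Disorders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for the integrated diagnosis of succinic semialdehyde
    dehydrogenase deficiency (SSADHD) and GABA-transaminase deficiency
    (GABA-TD): rule-based pathogenicity classification of ALDH5A1 variants
    from population allele-frequency tables, cumulative pathogenic allele
    frequency and Hardy-Weinberg carrier/prevalence estimation with
    CADD/SpliceAI-extended inclusion tiers, an untargeted-metabolomics
    z-score pipeline (anchor normalization, log transform, reference
    z-scores, abnormality flags) with GABA-pathway biomarker signature
    calls, an integrated molecular + biochemical diagnosis classifier with
    cohort summaries, and seeded synthetic-data generators emulating
    population variant tables and LC-MS intensity matrices for end-to-end
    testing without protected data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
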