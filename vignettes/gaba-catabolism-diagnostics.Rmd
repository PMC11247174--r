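---
title: "Methods: integrated diagnosis of GABA catabolism disorders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated diagnosis of GABA catabolism disorders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gabadx)
library(dplyr)
```

## The problem

Succinic semialdehyde dehydrogenase deficiency (SSADHD) is an autosomal
recessive disorder of GABA catabolism caused by biallelic pathogenic variants
in *ALDH5A1*. It is underdiagnosed: presentations are non-specific
(developmental delay, hypotonia, seizures), the classical biomarker (urine
4-hydroxybutyrate, GHB) is not always reliable, and sequencing alone
frequently returns variants of uncertain significance. This package
implements an integrated diagnostic workflow with four connected pieces:

1. **Variant rules** — deterministic pathogenicity classification of
   *ALDH5A1* variants from annotated population tables, with a
   prediction-extended inclusion tier.
2. **Prevalence** — cumulative pathogenic allele frequency and
   Hardy-Weinberg carrier/prevalence estimation per population.
3. **Metabolomics** — an untargeted-metabolomics z-score pipeline and
   GABA-pathway biomarker signature calls for SSADHD and GABA transaminase
   deficiency (GABA-TD).
4. **Diagnosis** — integration of molecular, biochemical and clinical
   evidence into a graded diagnostic status, plus cohort summaries.

A fifth module generates seeded synthetic data (population variant tables,
LC-MS-like intensity matrices, cohort tables) so that the entire pipeline is
testable end to end without access to protected databases or patient
samples.

## Variant classification rules

A variant is classified by the first matching rule:

1. a benign/likely-benign assertion excludes it (`excluded_benign`);
2. an allele frequency above `max_credible_af` in any population excludes it
   (`excluded_frequency`);
3. a previous report in a confirmed affected individual makes it
   `pathogenic` (unless it is a stop-loss variant, which stays a VUS);
4. a protein-truncating consequence — stop-gain, frameshift, start-loss, or
   a canonical splice variant at ±1/±2 bp — makes it `likely_pathogenic`;
5. everything else is a VUS. Stop-loss variants are never promoted to
   P/LP.

Exclusion always outranks evidence of pathogenicity, and the benign
assertion outranks the frequency rule. The published criteria give the
splice window once as "±0–2 bp" and once as "+/-1 and +/-2"; we use the
{1, 2} window, which is the usual definition of the canonical dinucleotides
— an offset-0 variant can still be rescued by SpliceAI in the extended
tier.

The inclusion tiers for prevalence estimation are:

* `base` — all P/LP variants;
* `extended_only` — VUS rescued by stringent computational prediction:
  missense with CADD PHRED ≥ 28.0, or any remaining variant with SpliceAI
  max delta ≥ 0.2 (both cutoffs inclusive). "Nonsynonymous" is read as
  missense-only for the CADD branch, because the published PHRED
  calibration is against known pathogenic missense variants; in-frame
  indels need explicit evidence. The SpliceAI branch is not restricted by
  consequence class ("potentially spliceogenic" is not a consequence).
* `excluded` — everything else. A base-tier variant can never also be
  counted `extended_only`, so the extended sum never double-counts.

`max_credible_af` defaults to 0.01 — far above any plausible single
pathogenic allele frequency for an ultra-rare recessive disorder, so it acts
only as a permissive guard against common polymorphisms. The published
analysis states only "greater than expected for disease"; the numeric guard
is a package choice and is configurable.

Variant identity is the cDNA-level HGVS string on one transcript
(NM_001080); protein-annotation discrepancies do not split a variant, and
mapping from the other reported transcript (NM_017040, one extra in-frame
exon) is input preparation, not rule logic. Reported percentages (novel
fraction, sex fractions) are truncated — not rounded — to one decimal,
matching the convention of the source case series (3/19 → 15.7%).

## Hardy-Weinberg estimation

With cumulative pathogenic allele frequency $q$ (the sum of qualifying
per-variant allele frequencies $AC/AN$ in a population):

$$\text{carrier frequency} = 2q(1-q), \qquad
  \text{disease prevalence} = q^2 .$$

We deliberately use the exact carrier form rather than the $2q$
approximation: inverting published carrier frequencies through
$q = \tfrac{1}{2}\bigl(1 - \sqrt{1-2c}\bigr)$ reproduces the published
prevalence denominators at their printed precision (e.g. a pan-ethnic
carrier frequency of 1/376 gives a prevalence of 1/564,000 at three
significant figures), which the approximation does not guarantee. Summing
per-variant frequencies assumes unlinked pathogenic alleles and ignores
phase — standard for ultra-rare recessive estimation; homozygote counts in
the source table are not treated specially.

Formatting follows the conventions of published prevalence tables: "1/N"
with N at 1–3 significant figures (3 by default), except that an exactly
integral N (e.g. a clinically referred frequency of 16 cases in 22,000
samples, 1 in 1,375) is displayed exactly. Populations with zero qualifying
alleles report "not estimable" rather than a denominator. The fold-increase
between tiers is the ratio of the "1 in N" denominators, one decimal.

```{r hwe}
q <- q_from_carrier(1 / 376)
hwe_estimates(q)
clinically_referred_frequency(16, 22000)
```

## The metabolomics pipeline

The z-score pipeline mirrors clinical untargeted metabolomics practice:

1. **Creatinine normalization** (urine only): each sample's intensities are
   divided by its creatinine, cancelling dilution.
2. **Anchor normalization**: each value is divided by the median intensity
   of that metabolite across the invariant anchor specimens of its
   analytical batch. Any batch-wide multiplicative factor cancels exactly;
   the median is chosen over the mean for robustness (the source protocol
   does not name a statistic).
3. **Log transform**: natural log. z-scores are invariant to the base as
   long as reference statistics use the same one, so the choice is purely
   internal.
4. **Reference statistics**: per-metabolite mean and sample SD
   (denominator $n-1$) of the log values across the reference cohort
   (default size 395). Constant metabolites are excluded; non-positive
   values are dropped with a warning.
5. **z-scores and flags**: $z = (\log v - \mu)/\sigma$; `high` at
   $z \ge 2$, `low` at $z \le -2$ — both inclusive ("equal to or greater
   than two standard deviations") — `not_reported` where the value is
   missing or non-positive.

### Signature calls

The SSADHD plasma signature requires both core markers — 2-pyrrolidinone
(the stable lactam of GABA) and 4-guanidinobutanoate (the arginine
transamidination product) — flagged high for a `positive` call. Adults with
SSADHD show an attenuated pattern: normal 2-pyrrolidinone with high-normal
4-guanidinobutanoate (published adult range z +1.70 to +2.38). A single
high core marker, or 4-guanidinobutanoate at or above the adult band
(default z ≥ 1.7), therefore yields `supportive`; we treat the band alone
as sufficient — elevated argininate or succinamic acid strengthens the
evidence string but is not required, since the attenuated adult profile was
itself observed without them. A missing core marker (older platform
versions did not report every analyte) makes the call `indeterminate`.

In urine the core pair is 4-guanidinobutanoate and succinimide;
2-pyrrolidinone carries no weight there (it is normal in urine even in
florid disease). CSF is unsupported — no CSF signature has been
established. The GABA-TD plasma signature is the analogous rule on
2-pyrrolidinone plus succinamic acid.

Raising any core marker's z can never demote a positive call; this
monotonicity is enforced by construction and tested.

### Age statistics

`age_group_stats()` fits an ordinary least-squares regression of a marker's
z on age (two-sided slope test) and compares pediatric (age ≤ 18 y) and
adult (age ≥ 19 y) groups with a pooled-variance, two-tailed Student's
t-test — pooled because the source analysis names Student's, not Welch's,
test. Ages are decimal years (6 months = 0.5). With non-integer ages the
boundary is implemented as pediatric ≤ 18 < adult.

## Integrated diagnosis

The diagnostic algorithm grades the evidence channels:

* **molecular criterion** — two P/LP alleles (homozygous or compound
  heterozygous; phase confirmation is carried when provided but not
  required, since case series are assembled from biallelic genotype
  listings);
* **biochemical criterion** — urine GHB above the 0–7 mmol/mol creatinine
  normal range (strictly; 7.0 is normal), a free-text "elevated
  GHB"/"abnormal" report, or a positive plasma signature;
* both → `comprehensively_confirmed`; molecular only →
  `molecularly_confirmed`; biochemical only → `biochemically_supported`;
  neither, but a suspicion-set clinical flag (developmental delay,
  hypotonia, seizures, ataxia, autistic features, speech delay, failure to
  thrive, stroke) or suggestive imaging → `suspected`; otherwise
  `not_supported`.

Cohort summaries count homozygous *subjects* (sibling pairs separately),
and compute demographics exactly as case series report them: mean age to
one decimal, exact median, sample SD, truncated percentages.

```{r cohort}
cohort_summary(ssadhd_cohort()) |> glimpse()
```

## Synthetic data: what it emulates, and what it does not

The generators define the study conditions under which the pipeline is
validated.

**Variant tables** plant a cumulative base-tier frequency (default
$1.33156 \times 10^{-3}$, the scale of the pan-ethnic estimate) split with
uniform random weights across truncating variants, plus an extended-tier
increment (default $7.8 \times 10^{-4}$) across CADD-qualifying missense
variants. In *exact* mode allele counts are planted as
$AC = \mathrm{round}(AF \cdot AN)$ (round-half-even) and the emitted truth
is the realized $\sum AC/AN$, so estimator recovery is exact by
construction; an allele too rare to reach one copy drops to zero with a
warning. In *binomial* mode $AC \sim \mathrm{Binomial}(AN, AF)$ and the
truth carries the planted $q$ with its binomial standard error.

**Intensity matrices** are log-normal per metabolite (location uniform on
log-intensity 2–8, scale 0.2–0.6 — a minimal model consistent with a
log-then-z pipeline; no heteroscedasticity or informative missingness).
Case samples carry planted z-shifts on their disease markers — the log
value is set to $\mu + z_\text{target}\sigma$ with $z_\text{target}$ drawn
uniformly within the published group ranges (pediatric plasma:
2-pyrrolidinone +3.12 to +6.50, 4-guanidinobutanoate +2.61 to +4.03; adult
plasma: +0.02 to +1.24 and +1.70 to +2.38; pediatric urine: succinimide
+2.09 to +3.16, 4-guanidinobutanoate +1.91 to +2.78). Only ranges are
published, hence the uniform draw; GABA-TD markers, published only as
"significantly elevated", default to [+3, +6]. Markers are simulated
independently — the within-disease covariance between, say,
2-pyrrolidinone and 4-guanidinobutanoate is unpublished, and this is a
known limitation. Anchors are truly invariant (planted at the metabolite
location) and every sample is multiplied by its batch's log-normal factor,
so anchor normalization is genuinely exercised. Decoy metabolites carry no
shift.

Because case markers have no individual biological noise on top of the
planted shift, the observed-vs-planted z deviation reflects only
finite-reference estimation error: with $n = 395$ the mean contributes
$\approx 1/\sqrt{395} \approx 0.05$ SD and the SD estimate
$\approx z_\text{target}/\sqrt{2(n-1)}$, giving a conservative bound of
±0.35 at the largest planted shifts, which the tests assert. Passing these
tests therefore shows the pipeline's arithmetic and invariances are
correct under the stated noise model — it does not certify performance on
real LC-MS data, where marker covariance, heteroscedastic noise, platform
drift and non-random missingness all exist.

**Cohort tables** use quota sampling (default 18 pediatric : 6 adult),
genotypes drawn from a pool of recurrent pathogenic alleles, and urine GHB
drawn above the normal range for cases (50–5,000 mmol/mol creatinine,
log-uniform) and inside it for controls.

## Numerical choices and degenerate inputs

* Percentage truncation uses `floor(x * 1000 + 1e-9) / 10` — the small
  epsilon guards exact decimal fractions against binary representation.
* "1/N" display prefers the exact integer when $|N - \mathrm{round}(N)| <
  10^{-9}$ (absolute, so large rounded denominators are never mistaken for
  integral ones).
* `q` is validated to $[0, 0.5]$ and carrier frequencies to $(0, 0.5]$;
  $q = 0$ propagates as "not estimable" rather than dividing by zero.
* A canonical-splice variant without a splice offset is a validation error
  (the ±1/2 window cannot be applied); absent CADD/SpliceAI scores simply
  fail their branch.
* Anchor coverage failures set values missing with a warning rather than
  erroring, so one bad metabolite/batch does not sink a run.
* Sizes used in the shipped validation suite (chosen to keep the full run
  in tens of seconds): reference cohorts of 395 for self-consistency and
  sensitivity checks, 1,000 replicates for the pediatric/adult separation
  property, 500 binomial replicates for planted-q recovery, 1,000 random
  draws for the closed-form Hardy-Weinberg and round-trip properties.

## Known limitations

* The rule engine covers the five published inclusion criteria, not the
  full ACMG/AMP framework; consequence annotation is an input, not a
  prediction.
* Prevalence estimates carry no confidence intervals (the source estimates
  publish none) and assume Hardy-Weinberg equilibrium within each
  population label.
* The adult supportive band (z ≥ 1.7) encodes a five-subject observation;
  it is configurable and should be re-derived as more adult data accrue.
* The reference population emulates a pediatric clinical reference; scoring
  adults against it inherits the same caveat as the source analysis.
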