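---
title: "Methods: birth-cohort selection scans, pleiotropy attribution, and liability-threshold prevalence prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cohortsel)
```

## Overview

`cohortsel` asks whether trait-associated alleles are under ongoing
natural selection, what that selection acts on, and what it does to
disease prevalence. The data model is a cross-sectional biobank:
individuals born across several decades, genotyped and phenotyped once
in mid-to-late adulthood. Birth cohorts then play the role of time
points — the frequency of an allele among people born in 1965–1969
versus 1940–1944 reflects (noisily) its change over 25 years of
births — subject to one important confound treated below.

This vignette documents the model, its assumptions, the tunable
parameters, the synthetic-data generator used for validation, and the
numerical and design choices made where the method description left the
choice open.

## Selection model

The selection coefficient is defined under complete dominance of the
beneficial allele: genotypes carrying at least one copy of allele *A*
(frequency *p*) have fitness 1 + *s*, the *aa* homozygote has fitness 1.
Deleterious alleles tend to be recessive, so a beneficial allele is
modeled as dominant. Under this model the per-generation change is

Δp = p·s·q² / (1 + s − s·q²),  q = 1 − p,

which for small *s* and moderate *p* is ≈ *p·s*. Over one generation
(25 years) the frequency therefore changes virtually linearly in time,
which motivates both the estimator and the generator:

* **Estimator** (`trend_test()`, `selection_coefficient()`): regress
  per-individual dosage/2 on birth year; the slope is the frequency
  change per year, and `s = slope × generation_years / p₀`.
* **Generator** (`simulate_allele_trajectory()`): apply the
  per-generation update (linearized `Δp = p·s` by default, or the exact
  dominant recurrence) at generation boundaries and interpolate
  linearly per birth year, clipping to [10⁻⁶, 1 − 10⁻⁶].

Two open choices were resolved as follows:

* **Individual-level vs cohort-level regression.** The trend test runs
  on individual dosages (n ≈ 10⁴–10⁵ points) rather than on the six
  cohort frequencies. Both have the same slope estimand (frequency
  change per year); the individual-level version uses the full sample
  and needs no within-cohort variance model. `scan_panel()` reports
  per-cohort frequencies alongside for inspection, and
  `scan_control_sets()` uses the same per-SNP test so the panel and its
  matched controls are scored identically.
* **The p₀ in s = Δp/p.** By default, the fitted frequency at the first
  cohort's midpoint year (intercept + slope × midpoint), which inherits
  the regression's noise averaging; `p0_method = "raw"` switches to the
  raw first-cohort frequency.

The rise/decline asymmetry among FDR-significant trends is tested with
an exact two-tailed binomial test at null 0.5, computed as
`min(1, 2 × smaller tail)`. At a symmetric null this coincides with the
"equally extreme outcomes" rule used by `binom.test()` (a unit test
checks the identity), and it reproduces printed two-tailed binomial
p-values such as 26 vs 6 → 0.00054.

## The lifespan confound and attribution

A frequency difference between the 1940s and 1960s cohorts of a
cross-sectional biobank can arise without any selection on birth: if an
allele shortens lifespan, its carriers are under-represented among the
(older) early cohorts at assessment time. `lifespan_screen()` tests
every panel SNP against the lifespans of the participants' mothers and
fathers separately (participant genotype is a noisy proxy for parental
genotype; in the generator the effect is planted directly on the
parental phenotypes for simplicity). A SNP significant for either
parent after per-trait FDR is excluded before the sign tests and the
prevalence model. The `lifespan_confounded` scenario plants exactly
this structure — frequency trends co-occurring with lifespan effects —
and the acceptance suite requires the flagged set to match the planted
set at Jaccard ≥ 0.8.

Selection surviving the screen is attributed to reproduction:
associations with age at first live birth (AFB, years) and number of
children ever born (NEB, counts) — the standard proxies for lifetime
reproductive success in industrialized populations. Direction
consistency is the antagonistic-pleiotropy sign logic: a positively
selected risk allele is consistent if it significantly lowers AFB
(earlier reproduction) or raises NEB; a negatively selected one if the
reverse. The overall count of consistent vs inconsistent SNPs gets an
exact binomial test. Two supporting analyses: Pearson correlation of
estimated *s* with the trait effect size among significant SNPs
(p-value via `t = r·√((n−2)/(1−r²))`), and a Pearson χ² (1 df, **no
continuity correction** — the uncorrected statistic is what reproduces
the reference contrast of 15/30 vs 3/30 → 11.4; Yates' correction would
give ≈ 9.6) comparing association proportions between the panel and
matched controls.

Group-level contrasts (myopic vs non-myopic AFB and NEB) use Welch's
t-test by default; the equal-variance pooled test is a switch. The
method description says only "two-tailed t-test", and Welch is the
safer default under unequal group variances.

## Association engine

All trait associations go through one engine: ordinary least squares of
the phenotype on risk-allele dosage plus an intercept and covariates
(default: exam age, sex, 10 principal components), two-tailed t-test on
the dosage coefficient, complete-case handling of missingness.
Degenerate designs (constant dosage after filtering, covariate
collinear with dosage) are flagged rather than given fabricated
estimates. The refractive-error association uses raw SpE with age as a
covariate (rather than the age-corrected SpE40) — matching the stated
covariate list; a corrected-phenotype analysis can be run by passing
`spe40` as the phenotype.

QC applies, in order, minor-allele count < 5, missingness > 0.05,
imputation info < 0.3 (skipped when no info scores exist), each a
strict inequality; a SNP carries only its first failure reason. LD is
computed from sample-dosage squared Pearson correlation — a deliberate
substitution for reference-panel LD lookup, which requires external
services; on synthetic data the sample is the population. Pruning is
greedy by association strength: visit SNPs in increasing p (ties broken
by smaller genomic coordinate, so results are deterministic), keep a
SNP only if its R² with every kept SNP is ≤ 0.8. For a mutually
correlated clique this keeps exactly the strongest member. A
`method = "random"` variant removes a random member per conflict for
robustness checks. FDR control is Benjamini–Hochberg (the description
names only "FDR < 0.05"); it is applied separately per trait family
(refraction, AFB, NEB, each parent's lifespan), matching the
per-analysis thresholds of the reference workflow.

## Liability-threshold prevalence model

The additive model standardizes genotypes per SNP,
`w = (x − 2p)/√(2p(1−p))` (mean 0, variance 1 under Hardy–Weinberg),
and forms `y_j = Σ w_ij·u_i + ε_j` with residual variance
`var(Σw·u)·(1/h² − 1)`, so the genetic score explains h² of the
liability variance. Choices:

* `p_i` is a single whole-sample frequency per SNP, so cohort
  differences enter only through the genotypes.
* `u_i` comes from the per-allele refractive-error betas via
  `u = −β·√(2p(1−p))` (`liability_effects_from_assoc()`): the √ factor
  moves a per-allele effect to the standardized scale, and the sign
  flip orients liability so larger = more myopia risk.
* Missing genotypes are imputed to `2p` (w = 0), neutral under the
  standardization.
* The threshold `y0` is the empirical (1 − target)-quantile
  (inverse-ECDF type) of the reference (first) cohort's scores, so the
  realized proportion above it matches the target within 1/n; the same
  threshold is reused for all cohorts and all replicates.
* Per replicate, fresh residuals are drawn and the threshold is
  re-calibrated on that replicate's reference scores; 100 replicates
  (default) are averaged, with the standard error over replicates
  reported.
* An all-zero `u` (null model) leaves `var(Σw·u) = 0` and the residual
  variance formula degenerate; the model then falls back to a
  unit-variance pure environmental liability, which keeps the
  calibration well defined and yields the expected flat prevalence.
  The generator uses the same convention.
* `h² = 0` is rejected at configuration time (residual variance
  undefined).

The last-minus-first cohort change in predicted prevalence (percentage
points) times the population, divided by 100, gives excess cases
(`excess_cases()`, rounded to the nearest case);
`fraction_of_increase()` expresses it against the total observed
prevalence change.

## The synthetic-cohort generator

`simulate_individuals()` instantiates exactly the statistical structure
the analysis assumes:

* Birth years uniform within each of six 5-year cohorts (1940–1969,
  the study conditions); exam years uniform in 2006–2010 with ages
  clamped to the aging schedule's range (40–70).
* Genotypes Binomial(2, p(birth year)) — Hardy–Weinberg within birth
  year — with p following the deterministic selection trajectory.
  Missing genotypes masked uniformly at `missing_rate`.
* Liability = standardized genetic score + Gaussian residual scaled to
  h² = 0.35 (the reported myopia SNP heritability, taken at the
  conservative end of 35–40%).
* Age-40 SpE is an affine map of liability with negative slope (higher
  liability = more myopic), with marginal SD 2.5 D (a realistic adult
  refractive spread), shifted so the first cohort's myopia prevalence
  equals the configured target (default 30.3%, the reference value).
  An environmental trend in birth year (D/year) is added before the
  calibration shift; the generator default is 0, and the `paper_like`
  scenario uses −0.03 D/year, chosen once so that the environmental
  contribution dominates the prevalence rise, as observed in real
  cohorts. No estimate of the real environmental component is implied.
* Observed SpE adds the scheduled hyperopic aging shift from 40 to the
  exam age (prorated inside 5-year bands) and splits into two eyes'
  sphere/cylinder (minus-cylinder convention; a switch handles
  plus-cylinder input) such that the eye-mean spherical equivalent is
  exact. Because the published 5-year age-band values are cited rather
  than printed in the reference description, the schedule is an
  explicit input everywhere, with a plausible synthetic default
  (+0.05 to +0.25 D per 5 years, accelerating); `correct_to_age40()`
  inverts whatever schedule generated the data exactly, and a test
  verifies the exact round trip.
* AFB ~ Normal(25, 4) years + genotype effects, defined only when
  NEB ≥ 1 (the real trait's support); NEB ~ Normal(2, 1.3) + effects,
  rounded and floored at 0; parental lifespans Normal(78/74, 10) years
  + genotype effects. Sex is Bernoulli(0.5); the 10 PC columns are
  standard Gaussian noise (they carry no population structure — the
  generator does not model stratification).

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: linkage disequilibrium
between panel SNPs (SNPs are independent; LD pruning is tested on
synthetic duplicated columns), population structure and its correlation
with birth year, genotyping/imputation error, informative missingness,
ascertainment into the biobank, and any causal pathway between
education, reproduction and refraction. The pipeline's conclusions on
real data rest on the original study design, not on these simulations;
the simulations establish that the estimators recover what was planted
under the model's own assumptions.

Scenario effect sizes are a scale choice: detecting a per-generation
s of ~0.02 requires cohort sizes near 50,000, so `generate_scenario()`
scales the planted |s| by `√(50000/n)` to keep the planted structure
recoverable at the reduced sample sizes used in examples and tests
(trend-slope standard error scales as 1/√n). Parameter-recovery checks
at the realistic operating point (s = 0.02, p₀ = 0.4, six cohorts of
50,000, median over 50 replicates, required within 10%) run in the
acceptance suite, which also verifies null calibration of the trend
test (rejection rate within [0.03, 0.07] at α = 0.05 over 1,000 null
SNPs), matched-control symmetry, liability calibration at
n = 10,000/cohort with 25 replicates, and the lifespan screen at
n ≈ 50,000. These problem sizes are the package's validation operating
points, chosen to make the Monte Carlo error small relative to each
tolerance.

## Matched-control resampling

`simulate_control_pool()` builds neutral pool SNPs by jittering
frequencies (±0.008) and recombination rates (±0.04 cM/Mb) around
panel values, guaranteeing admissible matches under the matching
tolerances (frequency ±1%, recombination ±0.05 cM/Mb).
`sample_matched_controls()` draws, per control set, one admissible pool
SNP per panel SNP uniformly **without replacement within a set**
(replacement across sets is allowed — the original procedure is silent,
and within-set exclusivity keeps each set a valid panel-sized draw). An
unmatched panel SNP is an explicit error naming the SNP. Control sets
are scored by the number of significant trends at the raw α per SNP
(each set is a marginal draw from an empirical null, so per-set FDR
would be both hyper-conservative under the null and unlike the
reference analysis, whose control sets averaged ~11 significant SNPs
of 213 ≈ 5%); a within-set FDR option exists.

## Numerical and degenerate-input conventions

* Trajectories clipped to [10⁻⁶, 1 − 10⁻⁶] inside the recurrence, so
  extreme parameters cannot diverge.
* `p₀` for the s-estimate clipped to the same range before division.
* Myopia is strictly `SpE < −0.5` (a record at exactly −0.5 D is not
  myopic).
* Exam ages outside [40, schedule max] are a hard error in
  `correct_to_age40()`.
* Cohort prevalence uses Wilson score intervals (well-behaved at small
  n and extreme proportions, unlike Wald).
* Constant dosage: the trend test returns slope 0 with a degenerate
  flag; the association engine returns `NA` estimates with the flag.
  Degenerate SNPs are excluded from FDR families.
* All randomness flows from explicit seeds; the pipeline derives
  per-stage streams from one master seed, so a config + seed pair
  reproduces the report byte for byte.

## Known limitations

* The dominant-fitness model is an assumption, not an inference; under
  additivity the same slope implies a different s.
* Frequency trends cannot distinguish direct selection from selection
  on linked variants; estimated s belongs to the haplotype, not
  necessarily the focal SNP.
* The lifespan screen is a proxy-based exclusion, not a correction:
  SNPs with lifespan effects below detection power remain in the panel.
* The liability model is purely additive (no dominance or epistasis)
  and takes h² as an input rather than estimating it.
* Statistical pleiotropy (association) is not biological pleiotropy;
  the attribution is correlational by design.
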