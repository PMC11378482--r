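---
title: "Methods: mean, variance and entropy mapping of aging methylomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mean, variance and entropy mapping of aging methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylaging)
```

# The problem

DNA methylation at a CpG site, measured over a bulk sample, is a fraction
in [0, 1] (a "beta value"). With age, some CpGs drift in their mean
methylation (DMPs), some grow more variable between individuals (VMPs),
and the methylome as a whole can drift toward the maximally uncertain
state where sites sit near 50% methylation — a rise in Shannon entropy.
These three phenomena are statistically distinct: a mean shift can occur
at constant variance, variance can grow around a fixed mean, and entropy
responds to where the mean sits relative to 50%, not to how fast it moves.
`methylaging` implements one coherent pipeline for all three, designed for
the realistic setting of many heterogeneous cohorts that must be analyzed
separately and pooled.

# Models and assumptions

## Per-cohort mean model (DMPs)

For each CpG, ordinary least squares of the M-value
(`M = log2(beta/(1-beta))`) on age plus cohort-specific covariates. The
M-scale is used for inference because beta values are heteroscedastic by
construction (variance vanishes near 0 and 1), while effects are reported
from a parallel beta-scale fit in percent methylation per year — the unit
in which array studies communicate effect sizes. The package deliberately
keeps both fits rather than back-transforming one into the other: the
back-transformed M-scale slope depends on the baseline, whereas the
parallel beta fit estimates the raw-scale trend directly.

Residual variances are moderated with empirical-Bayes shrinkage
(`limma::squeezeVar`; method-of-moments estimates of the prior df and
scale), which stabilizes small-cohort inference and reduces to plain OLS
t-statistics as the residual degrees of freedom grow. Moderation can be
disabled (`moderate = FALSE`), which is also how the implementation is
checked against a textbook normal-equations oracle.

Each cohort's summary statistics then pass through an empirical-null
bias/inflation correction: bias = median(z), inflation = normal-consistent
MAD(z); adjusted z = (z − bias)/inflation, with SEs scaled and effects
re-centered consistently. This is a deterministic moment-based stand-in
for mixture-model null estimation; it is exact when most CpGs are null and
conservative when signal is dense (the MAD then absorbs some signal and
the correction over-inflates SEs — coverage improves, power drops
somewhat). That trade-off is visible in the tests: class recovery is
validated *with* the correction enabled, at study scale.

## Per-cohort variance model (VMPs)

The Breusch–Pagan procedure on the same first-stage model: extract
residuals, square them, regress on age, and refer `LM = n·R²` of this
auxiliary regression to χ²(1). Two numerical points matter:

- The `n·R²` (studentized) form of the statistic is used. It does not
  assume Gaussian fourth moments, which bounded beta-derived data would
  violate; the type-I calibration criterion on Beta-distributed null
  methylomes passes because of this choice.
- Before testing, residuals are screened with Shapiro–Wilk at p < 1e-5
  (configurable). The screen exists to remove gross multimodality —
  typically CpGs under the influence of an unfiltered SNP, which would
  otherwise masquerade as variance signal. The threshold is deliberately
  extreme so the mild skew inherent to beta-derived residuals is kept.
  `stats::shapiro.test` caps at 5000 observations; larger cohorts are
  screened on their first 5000 samples in dataset order (deterministic).

The auxiliary slope's sign gives the direction of the variance change, so
the meta-analysis can be signed; its beta-scale analogue reports the
variance drift in fraction² per year.

## Meta-analyses

Mean effects pool by inverse-variance fixed effects (weights 1/se²), with
Cochran's Q and I² = max(0, (Q−(k−1))/Q)·100; the variance analysis pools
signed z-scores weighted by √n, because the BP statistic has no
effect/SE decomposition. Presence rules differ by design: mean-mode CpGs
need ≥ 3 cohorts; variance-mode CpGs need contributing cohorts covering
≥ 15% of all pooled samples (a sample-coverage rule, not a cohort count).
Log p-values are carried end to end (`pchisq(..., log.p = TRUE)`,
`qnorm(..., log.p = TRUE)`), so extremely significant CpGs never truncate
at the 2.2e-16 double-precision floor. Single-study records are flagged
(`k1`) rather than dropped, with I² reported as 0.

## Entropy

Per sample, on covariate-adjusted betas (M ~ covariates *without age*,
residuals plus the CpG's mean M, back-transformed — so age-driven structure
is preserved while batch/sex/BMI structure is removed):

Entropy = (1/(N·log2 ½)) Σ_i [MF_i·log2 MF_i + (1−MF_i)·log2(1−MF_i)]

The statistic is the mean binary entropy over CpGs: permutation-invariant,
exactly 1 when every CpG is at 50%, exactly 0 at 0%/100% (with
0·log 0 := 0 applied after clipping betas to [1e-6, 1−1e-6]), and additive
over disjoint CpG subsets (the entropy of a union is the size-weighted
mean). Entropy is regressed on age per cohort; slopes are standardized to
per-decade units everywhere (per-year OLS slope × 10) and pooled by
inverse-variance meta-analysis.

## Classification

DMP/VMP calls at meta-FDR < 0.005 combine into four joint classes.
Baseline methylation categories use inclusive thresholds (high ≥ 75%,
low ≤ 25%) computed in a young reference stratum: samples under 30 years
when at least 30 exist, else the youngest age tertile — a fallback needed
because cohort age windows differ. DMPs are *entropic* when the pooled
beta-scale slope points toward 0.5 from the baseline, *anti-entropic*
otherwise; a baseline of exactly 0.5 diverges under any nonzero slope and
is anti-entropic. The alternative operationalization (projected endpoint
crossing 0.5) was considered and rejected as the default because it
depends on an arbitrary projection horizon.

## Enrichment

Chromatin-state enrichment uses a χ² test per class against all remaining
CpGs, with signed Pearson residuals (O−E)/√E as the per-state
enrichment/depletion readout; the sum of squared residuals over the table
is exactly the χ² statistic, which the tests assert. States with expected
in-class counts below 1 merge into "other". Clock enrichment uses
Fisher's exact test on 2×2 tables restricted to each clock's own
background probe pool (clocks were trained on different array
generations, so a shared background would bias the odds ratios). The
reported OR is the sample cross-product (Haldane-corrected on zero
cells, 1 on degenerate margins) so it matches a hand-computed table; the
p-value is exact.

## Deconvolution

Cell fractions solve min‖b − Rw‖² s.t. w ≥ 0, Σw = 1, implemented as
non-negative least squares (`pracma::lsqnonneg`) followed by simplex
normalization. For well-conditioned references this equals the exact
quadratic program; the noiseless round trip in the tests recovers planted
fractions to 1e-6. Downstream adjustment uses the 5 most abundant types
(by cohort-mean fraction) as covariates — one type is always omitted
because fractions sum to one and would be collinear with the intercept.

# The synthetic-data generator

`generate_cohorts()` is first-class, tested code, and its defaults define
the conditions under which the pipeline is validated:

- **20 cohorts**, sizes drawn uniformly in [100, 2000], each with its own
  age window of width 30–60 years inside a global 20–90 range. Differing
  windows matter: they produce the between-cohort heterogeneity (I² > 0)
  and imperfect CpG overlap patterns the meta-analysis must tolerate.
- **Class structure**: 48% DMPs, 37% VMPs, 59% of DMPs also VMPs, 73% of
  DMPs entropic, 66% of extreme-baseline DMPs hypomethylating — the
  proportions reported for large blood-methylome compendia.
- **Mean slopes**: magnitudes uniform in [0.01%, 0.055%] methylation per
  year, bracketing the reported hypo/hyper averages (≈0.027–0.034%/yr)
  while staying well below the reported maxima (≈0.5%/yr).
- **Variance slopes**: target magnitudes uniform in [1e-5, 1e-4]
  fraction²/yr (the top reported VMPs average ≈1e-4), subject to a
  feasibility cap described below.
- **Generative law**: beta values are drawn per CpG per sample from a
  Beta distribution with age-linear mean on the *raw* scale (so planted
  slopes are in the units effects are reported in) and a precision
  schedule. Covariate effects (sex, batch, BMI) act on the logit scale at
  a sparse 10% of CpGs with random signs. The distributional form is a
  package choice — array data carry no such label — and beta-binomial or
  mixture alternatives would be defensible.
- **Variance feasibility cap**: a Beta variable cannot have variance
  approaching m(1−m), and strongly skewed Beta draws at extreme baselines
  produce M-value residuals that the pipeline's own Shapiro–Wilk screen
  would (correctly) remove. Variance slopes are therefore capped so the
  precision never falls below a floor (120 at extreme baselines, 40 at
  intermediate ones); the realized slope is what enters the ground truth.
  Without this cap the generator would plant VMPs that its own screening
  step is designed to reject — a self-inconsistent simulation.
- **Constant-variance trajectories**: for DMP-only and null CpGs the
  precision schedule holds the M-scale residual variance constant along
  the mean trajectory. Under a naive constant-precision law, a drifting
  mean mechanically drags variance with it (Var ∝ m(1−m)), which would
  make every DMP a VMP in expectation and the planted class labels
  meaningless.
- **Cell types**: 5% of age-null CpGs are cell-identity markers (lowly
  methylated in one of 6 leukocyte types, highly in the rest); per-sample
  proportions are Dirichlet draws around whole-blood means (Gran 0.58,
  CD4T 0.15, CD8T 0.08, Mono 0.08, NK 0.06, B 0.05). Proportion age-drift
  defaults to **0**: a nonzero drift deliberately plants composition
  confounding (null CpGs that test positive), which is the scenario the
  deconvolution-adjustment tests construct explicitly, not a background
  condition for class-recovery validation.

What the generator does **not** emulate: probe-type (I/II) chemistry and
normalization artifacts, spatial/batch structure beyond a single batch
factor, genotype-driven trimodality (except as a test fixture), missing
data (injection is opt-in), related individuals or repeated measures, and
nonlinear age trajectories. Passing tests therefore demonstrate the
statistical machinery is correct under the stated generative law, not that
real arrays are free of these additional complications.

# Numerical choices

- Betas are clipped to [1e-6, 1−1e-6] before any logit or entropy
  computation; `m_to_beta` uses the `1/(1+2^-M)` form, stable at extreme M.
- Tie/degenerate handling: zero residual variance → CpG flagged, not
  tested; constant entropy → slope 0 with se 0, flagged degenerate;
  k = 1 meta-records flagged `k1`; p = 0 inputs to the Stouffer pooling
  are clamped with a warning (log-p inputs avoid the issue entirely).
- Filtering order is fixed: samples first (detection failures), then
  probes — sample removal changes the per-probe failure fractions, so the
  reverse order would be ambiguous. Filtering is idempotent.
- Gating boundaries are inclusive ("fewer than 30" and "SD < 5" exclude,
  so n = 30 and SD = 5 pass), read literally.
- Probes failing detection anywhere are dropped (complete-case per probe)
  rather than imputed; downstream regressions assume complete vectors.

# Problem sizes used in validation

The test suite validates at these scales (chosen as the smallest that make
the statistical claims sharp): oracle equivalence on 100 random instances
per statistic; type-I calibration on 10 null cohorts of 1000 CpGs × 500
samples; class and effect recovery on the full default configuration
(20 cohorts, 2000 CpGs, ≈20k samples); the entropy mechanism on 10
seeded replicates of 3 cohorts × 250 samples; deconvolution on 200-marker
references with 60–100 samples. The complete suite runs in a few minutes
on one core.

# Known limitations

- The empirical-null correction is moment-based; under very dense signal
  it is conservative (inflated SEs, reduced power) relative to
  mixture-model alternatives.
- Fixed-effects pooling assumes one common effect per CpG; heterogeneity
  is *reported* (Q, I²) but not modelled. No random-effects option.
- The Shapiro screen trades a small loss of genuinely heteroscedastic
  CpGs (3–7% in simulation) for protection against SNP artifacts.
- Entropy is the plug-in estimator; no small-N bias correction is
  applied, which is immaterial for the thousands of CpGs typically used
  but would matter for very small subsets.
- The deconvolution reference is an input; the bundled generator produces
  synthetic references only, and estimated (not true) fractions carry
  their own error into adjusted analyses.
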