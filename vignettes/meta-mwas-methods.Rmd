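---
title: "Methods: meta-analysis of methylome-wide association studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-analysis of methylome-wide association studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metamwas)
```

This vignette is the package's account of the statistical machinery: the
models, their assumptions, the tunable parameters, the synthetic-data
generator used to validate every stage, and the design choices made
where the methodology left room.

## The analysis scale

Methylation is analyzed on the M-value scale, `m = log2(beta/(1-beta))`,
where beta is the methylated fraction in (0, 1). M values are
approximately Gaussian and variance-stable away from the boundaries,
which is what probe-wise linear regression assumes; `beta_to_m()` /
`m_to_beta()` convert between the scales for I/O.

## Cohort-level association model

For each probe, `run_probe_regression()` fits ordinary least squares
with the probe's M values as the dependent variable and case status as
the predictor of interest. Three nested covariate sets are supported:

* **basic** — age (years), sex, batch (one-hot, first level reference),
  the leading methylation principal components, and four of the five
  estimated white-blood-cell proportions. The fifth (granulocytes) is
  dropped deliberately: proportions sum to one, so including all five
  makes the design singular.
* **ahrr** — basic plus the M values of a smoking-proxy probe (the AHRR
  probe cg05575921 on real arrays). Smoking is a strong, trait-correlated
  driver of blood methylation, and this probe is a consistently measured
  surrogate; when the proxy probe is itself the outcome it is excluded
  from its own covariate set. This is the main model.
* **complex** — ahrr plus BMI and alcohol consumption, for sensitivity
  to those risk factors.

The case coefficient is reported as Cohen's *d* using the two-group
conversion `d = t(n1+n0)/(sqrt(n1 n0) sqrt(df))` with `se_d = d/t`
(the conversion factor itself at t = 0). The underlying method does not
pin down a specific t-to-d conversion, so the package uses this standard
one for regression-embedded two-group designs and documents it here;
`d/se_d` always reproduces the regression t statistic, so p-values are
identical on either scale.

Numerical notes: the per-cohort design is solved once by Cholesky
factorization of the cross-product and reused for all probes;
zero-variance probes are skipped and listed in an attribute rather than
raising an error (meta-analysis tolerates per-study missingness);
designs with condition number above 1e10 are rejected with the
offending columns named. The number of PCs defaults to 10 and is
truncated to what the design can support. PCs are computed on the
analyzed matrix itself. A caveat that matters at desk scale: when the
probe set is small (tens of probes) and planted effects are strong, the
leading components align with case status and absorb the signal being
estimated; several tests therefore disable PCs. On realistic matrices
(10^5–10^6 probes) no single probe can dominate a component and this is
not a concern.

## Two-stage fixed-effect meta-analysis

Studies are pooled by fixed-effect inverse variance:
`w_i = 1/se_i^2`, `beta = sum(w b)/sum(w)`, `se = 1/sqrt(sum(w))`, with
a two-sided normal p-value and no genomic-control correction. Pooling is
**two-stage**: first within each array (450K and EPIC probe sets
differ), then across the two array-level results per probe. IVW is
associative, so for any probe retained everywhere the two-stage result
equals one-stage pooling to machine precision — a property the test
suite asserts — but the staging makes the array-specific probe filters
natural to express:

* records with se > 0.5 (`se_max`) are dropped as uninformatively noisy;
* per array, a probe is retained if present in **more than half** of the
  array's studies (read strictly: 3 of 6 fails, 4 of 6 passes) **or**
  its summed analyzed n reaches 80% of the array's maximum possible
  total. The 80% boundary is read inclusively (`>=`) by default with a
  `n_rule_strict` flag, because the verbal rule ("over 80%") is ambiguous
  at the boundary; the sample-size rule is applied per array, where the
  stratified structure makes it well defined.

Bonferroni and BH-FDR are computed over all probes in the final pooled
table; `bonferroni_adjust(p, m)` takes the test count explicitly because
consortium analyses correct over the full probe universe (763,265 CpGs
in the emulated design) rather than the vector at hand. A per-study
direction string ('+', '-', '?') in a stable study order provides the
audit trail.

## DMR calling

Candidate regions are maximal runs of probes with meta p < 0.05 and a
shared effect sign in which every consecutive gap is at most 500 bp.
The window is interpreted as a **maximum gap between consecutive
probes** — the convention of summary-statistic DMR methods — not a bound
on total span; a `mode = "span"` switch provides the other reading.
Within a region, member statistics are pooled by generalized least
squares under covariance `S_ij = se_i se_j rho_ij`, where the
correlation is estimated as the Pearson correlation of member-probe M
values when a matrix is supplied and identity otherwise (summary
statistics alone cannot supply it). With identity correlation the GLS
reduces exactly to IVW; with perfectly correlated identical members it
returns the single-probe statistic (no spurious information gain) — both
limits are tested, including continuity at rho = 0.999.

The Bonferroni family for regions counts multi-probe regions and
singleton probes together. The region-size floor defaults to 2 probes;
because the source conventions state both "at least two" and "more than
two", the result carries both counts (`n_regions_min2`,
`n_regions_min3`) as attributes.

## Methylation scores

`build_weights()` selects probes at the five standard p-value thresholds
(1, 0.01, 0.001, 1e-6, 5e-8) and uses pooled effect sizes as weights;
weight sets are nested by construction. A sample's raw score is the
weighted sum of its M values; missing weighted probes are skipped and
counted. For evaluation the score is residualized (OLS against age, sex
and the smoking-proxy probe, then standardized) and the package reports
both orientations used in practice: the regression of score on case
status (so the coefficient is in score-SD units) and the Mann–Whitney
AUC of the score as a classifier, alongside the two-group Cohen's *d*.
Cell proportions are not forced into the evaluation model; following the
covariate-selection behavior of the emulated design they should be added
only if associated with the score, and the worked pipeline logs that
decision rather than hard-coding it.

The proteome scan transforms each protein's abundance by the rank-based
inverse normal transform with Blom offsets, `qnorm((r - 3/8)/(n + 1/4))`
with average ranks for ties (the tie rule is a package choice; rank
invariance is tested), residualizes against the protein-side covariates,
regresses on the score, and applies BH-FDR across proteins. Proteins
with strictly more than 40% of samples below the lower limit of
detection are removed first — at the emulated panel dimensions (92
proteins, 22 failing) this retains 70.

## Heterogeneity diagnostics

Leave-one-out meta-analysis re-pools the consortium k times, preserving
the array structure but with the presence/sample-size filters disabled
so each requested probe is pooled from whatever studies carry it; the
IVW combination of (left-out study, LOO rest) must reproduce the full
meta-analysis, which is asserted to 1e-10. Meta-regression of per-study
standardized coefficients on cohort mean age uses a mixed-effects model
with REML between-study variance via `metafor::rma`; with `method =
"FE"` it reduces to weighted least squares, the oracle used in tests.
Between-study agreement is summarized by effect-direction concordance
(zero effects counted non-concordant and flagged) and by Pearson
correlations of effect sizes over a reference study's top-k probes
(p-ranked with probe-id tie-break, so the selection is deterministic),
computed on complete-case overlap per pair with under-3-probe pairs
reported missing.

## Mendelian randomization

Forward (methylation → trait): for each CpG the most significant mQTL
within 1 Mb and below p = 5e-8 is the instrument (ties broken by larger
|beta|, then SNP id), harmonized against the trait GWAS, and the Wald
ratio `beta_out/beta_exp` computed with the first-order standard error
`se_out/|beta_exp|`. The first-order form is the convention for
single-instrument MR; a second-order option including the exposure
standard error is available. Reverse (trait → methylation): the trait
GWAS is clumped greedily (p ≤ 5e-8, 1 Mb, r² ≤ 0.001; LD is supplied as
a matrix rather than computed from a reference panel), each surviving
instrument yields a per-SNP Wald ratio against the mQTL outcome
statistics, and ratios are pooled by fixed-effect IVW per CpG — the
pooling rule for the reverse direction is not dictated by the emulated
design, so IVW was chosen and is noted here. Harmonization flips
swapped alleles (negating the outcome beta), drops mismatched allele
sets, and drops palindromic A/T and C/G SNPs with effect-allele
frequency in [0.42, 0.58] — a common default band, fixed here for
determinism. FDR is applied across tested CpGs; CpGs without usable
instruments are reported with reasons, not silently dropped.

## The synthetic-data generator

The generator emulates the study conditions the pipeline targets:
consortia of cohorts with tens to thousands of samples, case prevalence
from 6% to 63%, a mix of 450K and EPIC arrays (the 450K probe set a
strict subset of EPIC), and planted case–control effects expressed in
Cohen's *d* units relative to the residual M-value SD. M values are
simulated directly as Gaussian — the analysis operates on M values, so
no probe-level beta distribution is imposed — with additive confounding
through per-probe loadings (shared across cohorts, hence recoverable by
principal components) on age, sex, batch, four free cell proportions
(Dirichlet-style, summing to one with granulocytes dominant), a latent
smoking variable, BMI and alcohol. Smoking is deliberately a
*mis-measured* confounder: the latent variable is correlated with case
status (slope 0.3) and observed only through a proxy probe
(0.8 × latent + noise), mimicking the AHRR covariate's role. Residual
confounding through this channel leaves a small genomic inflation
(lambda around 1.00–1.05 at large n) — realistic for adjusted EWAS.
Genotypes are binomial(2, MAF) under Hardy–Weinberg; SNP→CpG→trait
chains and protein panels plant linear slopes with unit noise. A single
master seed spawns deterministic per-cohort streams, so cohort output
does not depend on cohort order, and identical (config, seed) reproduces
byte-identical artifacts.

What the generator does **not** emulate: realistic per-probe beta-value
distributions, chip/plate batch geometry, family relatedness, population
stratification, or surrogate-variable-specific artifacts (only
PC-recoverable structure is planted). Passing tests therefore
demonstrate correctness of the estimators under the stated model, not
robustness to every failure mode of real array data.

## Problem sizes and defaults

The validation suites run at deliberate desk scale: null family-wise
error uses 20 consortium replicates of 10 cohorts × 5,000 probes at
n = 100 per cohort; power uses one consortium of 10 cohorts × 2,000
samples (total n = 20,000) with ten planted d = 0.2 effects, the effect
magnitude and total n typical of the consortium designs emulated; DMR
recovery uses 20 replicates of 4 cohorts × 300 samples with a planted
3-probe block at d = 0.3; score evaluation uses 504 cases and 8,372
controls with a planted shift of d = 0.1, bracketing an AUC near 0.53;
MR recovery uses n = 5,000–20,000 with an mQTL slope of 0.4 and a causal
slope of 0.05. These sizes were chosen once as representative of the
emulated designs and give comfortable Monte-Carlo margins for the
assertions attached to them.

Key defaults, with units: `se_max = 0.5` (d units), `presence_fraction
= 0.5` (strict), `n_fraction_of_max = 0.8` (inclusive), `max_gap = 500`
bp, score thresholds {1, 0.01, 0.001, 1e-6, 5e-8}, MR window 1 Mb,
instrument threshold 5e-8, clumping r² 0.001, LLOD failure threshold
0.40 (strict), noise_sd 1 (M units).

## Known limitations

Fixed-effect pooling assumes a common true effect per probe;
between-study heterogeneity is diagnosed (LOO, correlations,
meta-regression) but not modeled by random effects, matching the
emulated design's choice. The DMR correlation defaults to identity when
no M-value matrix is available, which overstates regional information
for tightly correlated probes. The Wald-ratio se ignores exposure
uncertainty unless the second-order option is used, and single-SNP MR
cannot detect pleiotropy — the pleiotropy-robust multi-instrument
estimators are out of scope. The probe-regression p-values rely on
large-sample normality of OLS; cohorts with very few cases (the
generator floor is one case) yield unstable d estimates that the se
filter is designed to catch downstream.
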