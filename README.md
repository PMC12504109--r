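# metamwas

Meta-analysis of methylome-wide association studies (MWAS) for a binary
trait, built for consortium settings in which cohorts profile DNA
methylation on different Illumina arrays (450K and EPIC), vary widely in
size and case prevalence, and only share summary statistics. The package
grew out of the analysis design used for large case–control depression
consortia, but every stage is generic: it consumes post-QC M-value
matrices and standard summary-statistic tables.

The pipeline covers:

- **Per-cohort MWAS** — probe-wise OLS of M values on case status under
  three covariate models (basic; + smoking-proxy probe; + BMI/alcohol),
  with effects standardized to Cohen's *d*,

  *d* = *t* (n₁+n₀) / (√(n₁n₀) √df),  se(*d*) = *d*/*t*.

- **Two-stage fixed-effect meta-analysis** — inverse-variance weighting
  (wᵢ = 1/seᵢ², β̂ = Σwᵢβᵢ/Σwᵢ, se = 1/√Σwᵢ) within each array, then
  across arrays, with the consortium probe-inclusion filters: a probe is
  kept per array if present in more than half of that array's studies or
  carrying ≥ 80% of the array's maximum total n; records with se > 0.5
  are dropped first. Bonferroni and Benjamini–Hochberg corrections over
  the pooled table; no genomic-control correction.
- **DMR calling** — maximal runs of nominally significant (p < 0.05),
  direction-consistent probes with consecutive gaps ≤ 500 bp, pooled by
  generalized inverse-variance with the inter-probe correlation
  Σᵢⱼ = seᵢseⱼρᵢⱼ, Bonferroni-corrected over regions and singletons
  together.
- **Methylation scores** — per-sample weighted sums of M values at five
  p-value thresholds (1, 0.01, 10⁻³, 10⁻⁶, 5×10⁻⁸), residualized and
  evaluated out of sample (regression beta, Mann–Whitney AUC, Cohen's
  *d*), plus a proteome-wide association scan with a rank-based inverse
  normal transform and a >40% below-LLOD detection filter.
- **Heterogeneity diagnostics** — leave-one-out meta-analysis, REML
  meta-regression of study effects on cohort mean age, effect-direction
  concordance, and pairwise between-study effect-size correlations.
- **Bidirectional two-sample Mendelian randomization** — cis-mQTL
  instrument selection (1 Mb window, p < 5×10⁻⁸), greedy LD clumping
  (r² ≤ 0.001), allele harmonization with palindromic-SNP filtering, and
  Wald ratios β = β_out/β_exp with se = se_out/|β_exp|.
- **A synthetic-data generator** — multi-cohort 450K/EPIC consortia,
  SNP→CpG→trait causal chains, and a 92-plex protein panel with a lower
  limit of detection, all with planted ground truth, so every stage can
  be validated against known effects.

## Worked example

Simulate a four-cohort mixed-array consortium with four isolated planted
effects (d = 0.4) and one three-probe DMR block (d = 0.3), run the
cohort MWAS under the smoking-adjusted model, pool, and call DMRs:

```r
library(metamwas)
cfg <- sim_config(n_cohorts = 4, n_samples = c(300, 400, 500, 600),
                  case_prevalence = c(0.15, 0.25, 0.35, 0.5),
                  array = c("450K", "450K", "EPIC", "EPIC"),
                  n_probes_shared = 1000, n_probes_epic_only = 200,
                  n_causal = 4, effect_size_d = 0.4,
                  n_dmr_blocks = 1, dmr_block_size = 3, dmr_block_d = 0.3,
                  seed = 2026)
sim   <- simulate_consortium(cfg)
stats <- lapply(sim$cohorts, run_probe_regression, model = "ahrr")
meta  <- two_stage_meta(stats)
print(meta, n = 5)
#> <meta_result> 1200 probes pooled from 4 studies; 7 Bonferroni-significant at m = 1200
#>      probe chr    pos      beta         se        z            p p_bonferroni ...
#>  cg1000993  13  71493 0.4542865 0.05264653 8.628992 6.189506e-18 7.427408e-15
#>  cg1000770   1  59083 0.4303422 0.05264653 8.174180 2.978842e-16 3.574610e-13
#>  cg1000854  17 107589 0.3749565 0.05264653 7.122150 1.062565e-12 1.275078e-09
#>  cg1000700  16  98639 0.3672192 0.05264653 6.975183 3.054728e-12 3.665674e-09
#>  cg1000404   9  63330 0.3644425 0.05264653 6.922441 4.439281e-12 5.327137e-09

dmrs <- call_dmrs(meta, sim$truth$manifest,
                  m_values = sim$cohorts[[1]]$m_values)
print(dmrs, n = 1)
#> <dmr_result> 52 candidates (1 multi-probe), 1 significant DMRs; m_tests = 52
#>  chr start   end n_probes                        probes     beta ...
#>    9 63180 63480        3 cg1000220;cg1000404;cg1000764 0.331992
```

All seven Bonferroni-significant probes are the planted ones
(`sim$truth$causal_probe_ids`): the four isolated effects recovered near
d = 0.4 with positive direction in all four studies (`++++`), and the
only significant DMR is exactly the planted block on chromosome 9, whose
pooled estimate 0.33 sits close to the planted 0.3. The inflation factor
`genomic_inflation(meta$p)` is 0.88 — near 1, as expected when the
covariate models match the confounding structure.

`run_pipeline(list(seed = 1, sim = list(...)), out_dir)` executes the
whole chain (simulate → MWAS → meta → DMR/score/heterogeneity/MR) and
writes TSV/JSON artifacts plus a run manifest with input hashes.

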