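# microGBLUP

Microbiome-assisted multi-trait genomic evaluation of longitudinal growth
in beef cattle.

`microGBLUP` is an R package for quantitative geneticists who want to use
rumen microbial gene abundances (KEGG orthologs, "MG") as correlated traits
in genomic evaluation of stage-wise average daily gain (ADG). It covers the
full chain from raw inputs to selection decisions:

* **Growth traits** — four stage-wise ADG (kg/day) as 5-point OLS slopes of
  weekly weights on recorded days (shared window boundaries: points 1–5,
  5–9, 9–13, 13–17).
* **Genotypes** — SNP/animal quality control (call rate ≥ 95%/90%,
  MAF ≥ 0.05, Hardy–Weinberg p ≥ 1e-8) and the VanRaden Method-2 genomic
  relationship matrix `G = (1/m) Σ zᵢzᵢ′ / (2pᵢ(1−pᵢ))`.
* **Microbiome compositions** — 70% core-presence filter, geometric
  Bayesian-multiplicative zero replacement, data-driven additive log-ratio
  (alr) reference selection (Procrustes correlation vs the clr geometry,
  then minimum log-abundance variance), and the alr transform itself.
* **Bayesian GBLUP** — a Gibbs sampler for `y = Xb + u + e` with
  `u ~ N(0, G ⊗ K)`, `e ~ N(0, R ⊗ I)`: univariate to 36-trait models,
  missing-phenotype augmentation, optional fixed covariances, accelerated
  by GRM eigendecomposition plus joint diagonalisation of (G, R). Posterior
  summaries: median, shortest 95% HPD, P0, Geweke Z, batch-means MCSE.
* **Estimation campaign** — per-MG h² scans, MG×ADG genomic-correlation
  scans with P0 ≥ 0.85 cataloguing, ADG parameters from six pairwise
  bivariate models with pooled h² chains, permutation nulls, prior
  sensitivity.
* **Covariance assembly** — multi-trait G and R from pairwise estimates;
  bending by eigenvalue flooring (tolerance 1e-3) with SE and h²-shift
  validation.
* **MG subset selection** — candidate filtering (P0 and relative
  abundance ≥ 0.001%), optional uniform-rg-sign restriction, round-robin
  forward-AIC selection of 8 MG per ADG trait on GEBV.
* **Breeding strategies** — direct / microbiome-driven / combined
  evaluations with fixed covariances; accuracy
  `√(1 − sdᵢ²/(gᵢᵢσᵤ²))`, selection intensity `φ(Φ⁻¹(1−p))/p`, and
  predicted truncation-selection response from GEBV posterior draws.
* **Synthetic data** — a first-class generator reproducing the study
  structure (359 + 30 sire-structured animals, 17 weekly weights with stage
  means 1.57/1.50/1.48/1.41 kg/day, h² 0.27–0.31, a 17-level fixed effect,
  multinomial counts with structural zeros, a stable alr reference trait)
  with full ground truth for parameter-recovery validation.

## Worked example

```r
library(microGBLUP)

# Simulate a sire-structured population with known parameters
cfg <- sim_config(n_animals = 400, n_sires_extra = 30, n_snps = 2000,
                  n_mg = 10, h2_mg = rep(0.33, 10),
                  genetic_corr = default_genetic_corr(10, mg_rg_range = c(0.3, 0.3)),
                  depth_range = c(1e6, 2e6), seed = 1)
sim <- simulate_dataset(cfg)

# Growth traits and GRM
adg <- adg_table(sim$weights)
K   <- sim$grm[adg$animal, adg$animal]

# Heritability of first-stage gain
fit <- gibbs_sample(as.matrix(adg[, -1])[, 1], factor(sim$fixed$level), K,
                    mcmc = mcmc_settings(3000, 750, 5, seed = 1))
derive_genetic_parameters(fit)$h2_summary
#>    trait    median hpd95_low hpd95_high         sd p0 ...
#> 1 trait1 0.3424173 0.2099279  0.5278959 0.08138937  1 ...

selection_intensity(0.10)
#> [1] 1.754983
```

The h² median 0.34 with HPD95 [0.21, 0.53] recovers the simulated 0.31
(the generator's default heritability of first-stage gain); the interval
width is what ~400 animals support. `run_strategy()` then compares evaluations: on
these data the combined strategy reaches a mean GEBV accuracy of 0.66
versus 0.61 direct and 0.41 microbiome-only, and `predicted_response()`
converts top-10% selection into kg/day responses.

An end-to-end orchestration (simulation or TSV inputs → ADG → GRM →
compositions → scans → assembly → selection → strategies, with per-stage
caching and TSV/JSON artifacts) is available via `run_pipeline()`.

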