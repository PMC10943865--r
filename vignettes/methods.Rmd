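---
title: "Microbiome-assisted genomic evaluation of longitudinal growth: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microbiome-assisted genomic evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(microGBLUP)
```

## The problem

Growth rate in finishing beef cattle changes over time, and the rumen
microbiome is partly under host genetic control. `microGBLUP` implements a
complete evaluation chain for asking two linked questions: (i) are the
abundances of microbial gene functions (KEGG orthologs, "MG") genomically
correlated with stage-wise average daily gain (ADG), and (ii) does including
such microbial traits in a multi-trait genomic evaluation improve the
accuracy of breeding values and the predicted response to selection?

The chain is: weekly weights → four stage-wise ADG traits; SNP genotypes →
quality control → a VanRaden Method-2 genomic relationship matrix (GRM);
microbial counts → compositional processing → additive log-ratio (alr)
traits; Bayesian uni-/bi-/multivariate animal models by Gibbs sampling;
assembly and bending of large covariance matrices from pairwise estimates;
forward-AIC selection of an informative MG subset; and evaluation of direct,
microbiome-driven and combined breeding strategies.

## Growth traits

Seventeen weekly weights per animal span four 4-week stages. `ADG_k` is the
ordinary-least-squares slope (kg/day) of weight on recorded day over five
weight points. Four windows of five points over 17 records force shared
boundary points (1–5, 5–9, 9–13, 13–17); that window layout is the only one
consistent with the record counts. Regression on actual day offsets (not
week indices) tolerates schedule jitter. Measurement noise of a few kg per
weighing propagates to a slope standard error of `noise_sd / sqrt(490)` ≈
0.05 kg/day per 1 kg of noise, which is small against the phenotypic
standard deviation (~0.42 kg/day).

## Genotypes and the GRM

QC removes SNPs with call rate < 95%, minor allele frequency < 0.05, or
Hardy–Weinberg deviation at p < 1e-8, then animals with call rate < 90%;
residual missing dosages are mean-imputed per SNP. The Hardy–Weinberg rule
is applied as *removal when p is below* the threshold: the direction
printed in some method summaries ("P > 1e-8") would discard nearly every
SNP and cannot be meant literally. The GRM standardises each SNP by its
observed allele frequency: `G = (1/m) Σ z_i z_i' / (2 p_i (1-p_i))`,
`z_i = dosage − 2 p_i`, so the diagonal averages ~1 under Hardy–Weinberg
equilibrium. Observed (not base-population) frequencies are used because no
pedigree base population is defined.

## Compositional processing

Sequencing counts are compositional: only relative information is
interpretable. The pipeline is:

1. **Core filter** — keep MG present (nonzero) in at least 70% of samples
   (`ceiling(0.70 × 359) = 252` at full scale); the retained fraction of
   total counts is reported.
2. **Zero replacement** — geometric Bayesian-multiplicative imputation:
   zeros in a sample of depth `n` become `t_j · s/(n + s)` where `t_j` are
   prior proportions from column geometric means and `s` is the prior
   strength; non-zero parts are rescaled multiplicatively, so their ratios
   are untouched. The cited method fixes the form, not the hyperparameters;
   we default to `s = sqrt(mean depth)` and document both as configurable.
3. **alr reference selection** — a good reference preserves the exact
   log-ratio geometry (measured as the Procrustes correlation between the
   centred clr configuration and each candidate alr configuration:
   `Σσ(A'B)/sqrt(tr(A'A)·tr(B'B))`) and has low variance in its own log
   relative abundance, so alr values read as numerator properties. The
   published account reports the outcome of this trade-off, not a rule; we
   operationalise it as "top decile by Procrustes correlation, then minimum
   variance", both knobs configurable.
4. **alr transform** — `ln(x_j / x_ref)`; the inverse (softmax with a zero
   at the reference) reproduces the composition to machine precision.

## The genomic animal model and its Gibbs sampler

All genetic analyses use

$$y = Xb + u + e,\qquad u \sim N(0,\, G \otimes K),\qquad e \sim N(0,\, R \otimes I),$$

with `K` the GRM, flat priors on `b`, and conjugate priors on the
(co)variances: scaled-inverse-chi-square (univariate) or inverse-Wishart
(multivariate) with prior degrees of freedom 5 (residual; and univariate
genomic) or 3 (multivariate genomic) and scale
`S0 = var(Y)·(df0 + t + 1)·R2`, `R2 = 0.5`. This scale convention follows
the Bayesian GBLUP software tradition: `S0` enters the conditional
numerator directly, i.e. it already equals `df0` times the textbook per-df
scale, and makes the prior mode of each variance `R2·var(Y)`. The exposed
conditional sampler `sample_variance_conditional(quad, q, df0, S0)` draws
`(quad + df0·S0)/χ²(df0+q)` with the textbook scale, and the model code
passes `S0/df0` to it accordingly.

Sampler design:

* **Rotation acceleration.** One eigendecomposition `K = V D V'` per fit,
  plus a per-iteration joint diagonalisation of `(G, R)` (Cholesky of `R`,
  eigendecomposition of `L⁻¹ G L⁻ᵀ`), renders every animal × trait
  coordinate of the breeding-value update conditionally independent, so the
  update is elementwise matrix algebra. This is what makes scans over
  thousands of microbial traits feasible, and it is mathematically exact.
* **Missing phenotypes** are sampled from their conditional normal per
  missingness pattern (data augmentation). Animals with genotypes but no
  records (sires) and the microbiome-driven strategy (all ADG records
  missing) are both just missingness patterns.
* **Numerics.** A numerically singular GRM gets +1e-6 on its eigenvalues.
  Rank-deficient fixed-effect designs and non-positive-definite fixed
  covariance matrices are rejected with diagnostics.
* **Summaries.** Chains are summarised by the median, the shortest
  (Chen–Shao) 95% HPD interval, `P0` (posterior probability of sharing the
  median's sign), a Geweke Z (first 10% vs last 50%, AR-spectral variance),
  and batch-means MCSE with a flag for `MCSE ≤ sd/10`. A constant chain
  returns an NA Geweke flag rather than an error.

Default chain lengths follow the published settings (500k/100k/50 for
parameter estimation; 100k/20k/100 for breeding-value runs) but every run
in this package's tests and examples uses documented short chains (3000
iterations, 750 burn-in, thin 5) — posterior medians at these lengths were
verified against 10× longer chains.

## The estimation campaign

Per-MG heritability uses one univariate model per alr-MG; MG×ADG genomic
correlations use four bivariate models per MG; correlations are catalogued
as non-zero when `P0 ≥ 0.85`. ADG genetic parameters come from the six
pairwise bivariate models, pooling each trait's three h² chains. Every
sub-model's seed is derived deterministically from the master seed and the
trait identifier, so scans are order-independent and resumable. Permutation
nulls permute the phenotype vector only (the fixed-effect design stays with
the genotypes; carrying it along is a switch). Prior sensitivity re-runs
designated models over a df0 grid with `S0` recomputed each time.

## Covariance assembly and bending

The multi-trait evaluations need full `t × t` genomic and residual
matrices, assembled from pairwise bivariate estimates: off-diagonals from
the unique model for that pair, diagonals as the arithmetic mean of the
trait's variance estimates across models (the unbiased combination that
avoids re-running models). Assembled matrices are usually not positive
definite; bending floors eigenvalues at 1e-3 and reconstructs, which keeps
eigenvectors, is idempotent, and is a no-op on matrices already above the
floor. Validation checks — entrywise change within the posterior SE and
relative h² shift within 5%, both inclusive — are reported per entry/trait.

## MG subset selection

Candidates require `P0 ≥ 0.85` against at least one ADG trait and mean
relative abundance ≥ 0.001% (as a proportion, 1e-5): low-abundance genes
are kept out because their counts carry more technical variation. (One
published sentence inverts this direction; the results tables make clear
that the abundant genes are the ones retained, and that is what is
implemented.) The uniform-sign variant additionally requires all four rg
medians to share a sign; an exact zero asserts no sign and is excluded.

Selection is round-robin forward regression on GEBV: cycling ADG₁→ADG₄, the
dependent variable is the current trait's GEBV, predictors are the other
three ADG GEBV, all previously selected MG GEBV, and one candidate; the
candidate minimising `AIC = n·ln(RSS/n) + 2k` joins (constant terms
omitted; ties break lexicographically by MG id). Stopping is the fixed
count of 4 × quota (8 per trait at full scale). Adjusted R² per trait of
the final model is reported and is monotone against the ADG-only baseline.

## Breeding strategies, accuracy and response

Three evaluations with fixed (assembled, bent) covariances: **direct**
(tetra-variate, ADG only), **microbiome-driven** (ADG records set missing;
only MG observed) and **combined** (both observed). GEBV are posterior
means of `u`; per-animal accuracy is
`sqrt(1 − sd_i²/(g_ii·σ_u²))` — the posterior uncertainty relative to the
prior genomic variance. Finite chains can push `sd_i²` past `g_ii σ_u²`;
such accuracies are clipped to 0 and counted rather than propagating NaN.
Mean accuracy is reported over all animals and over phenotyped animals.

Truncation selection at proportion `p` has intensity `i = φ(Φ⁻¹(1−p))/p`
(1.755 at p = 0.10). Predicted response per trait fixes the selected set by
posterior-mean GEBV ranking, then computes `mean(selected) − mean(all)` per
retained draw; the sign convention makes upward selection positive. Equal
economic weights are implemented as independent per-trait rankings.

## The synthetic-data generator

The generator emulates the study conditions: 359 phenotyped animals plus 30
genotyped-only sires (desk-scale analyses use 400 + 30), 17 weekly weights
with stage means 1.57/1.50/1.48/1.41 kg/day, ADG heritabilities
0.31/0.27/0.29/0.27 with rg(ADG₁,ADG₃) = 0.39, a 17-level fixed effect, MG
heritabilities drawn from 0.19–0.44, MG–ADG genomic correlations up to
|0.42|, and multinomial counts at variable depth with natural structural
zeros. Choices the source material does not pin down, fixed once here:

* **Phenotypic scale.** ADG phenotypic variance 0.18 (kg/day)² (CV ≈ 28% of
  a ~1.5 kg/day mean, the middle of the reported 25–32% range); latent MG
  log-abundance variance 1; fixed-effect level sd 0.1 kg/day; weighing
  noise 2 kg; initial weights ~N(450, 40²) kg.
* **Relatedness.** By default the phenotyped animals are half-sib offspring
  of the genotyped sires (`structure = "sire"`); marginally every allele is
  still a Bernoulli draw at the SNP's frequency. A cattle population of
  unrelated individuals would leave genomic variance components nearly
  unidentifiable at n ≈ 400 — the sire families are what carry the
  information in the real design. Fully unrelated sampling remains
  available for unit tests.
* **Stable reference trait.** One extra microbial trait with zero
  heritability and residual variance 0.02 emulates the stable
  reference gene used for the alr transform (the real reference has
  log-abundance variance 0.038, CV 5%). With it, alr-MG values equal the
  latent MG traits up to an almost-constant shift, so generator truth
  survives the compositional pipeline.
* **Residual independence.** Environmental correlations between traits are
  set to zero (the reported ones are −0.17…0.05 and inconsistent in sign);
  within-animal weight noise is i.i.d., as nothing in the source describes
  autocorrelation.
* **PSD construction.** The default genetic correlation matrix embeds each
  MG trait as a unit vector with the target projection on the ADG block, so
  it is positive semidefinite by construction. User-supplied matrices that
  are not PSD are rejected, never silently bent — bending is an analysis
  stage, not a simulator fix.

What passing recovery tests on these data does **not** show: robustness to
linkage disequilibrium (loci are independent), genotype-by-environment
effects, breed stratification confounding, non-Gaussian microbial noise, or
real sequencing artefacts. The generator validates the estimation
machinery, not the biology.

## What the tests assert, and one honest limitation

The acceptance suite checks, at documented desk scales: the analytic
selection intensity; the variance full conditional against its closed form
(Kolmogorov–Smirnov); equivalence of posterior-mean breeding values with
the direct mixed-model-equations BLUP (fixed covariances); parameter
recovery over 20 seeded replicates; the strategy ordering (combined >
direct, microbiome-only informative); bending behaviour on engineered
36-trait matrices; compositional round-trips and geometry preservation;
the stepwise oracle; exact ADG slopes; and separation of the permutation
null from a real heritability signal.

One recovery aspect does not meet its nominal tolerance and is deliberately
left failing rather than loosened: posterior medians of genomic
correlations at n = 400 shrink toward the prior mode (roughly the
phenotypic correlation), e.g. seed-averaged rg(ADG₁,ADG₃) ≈ 0.16–0.2
against a simulated 0.39. This is not a sampler defect (recovery is
accurate at n ≈ 1200, and 10× longer chains reproduce the same medians) but
an information limit: a maximum-likelihood oracle on identical data has a
seed-to-seed standard deviation of ≈ 0.155, so no estimator can pin these
correlations to ±0.12 at this sample size. HPD-interval coverage — the
calibration property a Bayesian analysis owes — is ≥ 80% throughout, and
the same prior dependence at small n is acknowledged in the source
analyses' own sensitivity checks.

## Problem sizes used by tests and the acceptance script

Recovery and strategy checks use n = 400 phenotyped animals from 30 sires,
2000 SNPs, 10 microbial traits plus the stable reference, sequencing depths
1–2 × 10⁶, and 3000-iteration chains (750 burn-in, thin 5; 1500/400/4 for
fixed-covariance breeding-value runs). Compositional geometry checks use 50
samples × 150 parts. These sizes were chosen as the smallest at which the
statistical properties under test are expressed clearly.
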