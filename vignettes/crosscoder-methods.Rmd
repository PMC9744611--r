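---
title: "Inferring the direction of cross-disease association from paired autoencoder pseudogenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the direction of cross-disease association from paired autoencoder pseudogenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosscoder)
```

## The problem

Two diseases — the motivating case is Alzheimer's disease and lung cancer,
each assembled from several public microarray studies on a common
platform — may share many differentially expressed genes (DEGs) and yet
resist any statement about the *direction* of their association: typically
some shared DEGs move the same way in both diseases and others move in
opposite ways, in comparable numbers. Counting concordant versus
discordant genes therefore gives no unified answer.

`crosscoder` resolves this by learning, per disease, a one-dimensional
summary of the shared-DEG expression profile (a "pseudogene"), and then
correlating the two summaries on held-out patients. Because each summary
is a single number per sample, the sign of their rank correlation is a
single, unified direction estimate.

## The pipeline and its assumptions

### Batch adjustment

Each cohort aggregates several studies, so residual study effects are
removed per cohort with the classic location/scale parametric
empirical-Bayes procedure (`combat_adjust()`): gene-wise standardisation
after a least-squares fit of batch means, per-(gene, batch) location and
scale estimates, shrinkage under a normal prior on locations and an
inverse-gamma prior on scales (hyperparameters by method of moments, the
coupled posterior updates iterated to a relative change below `1e-4`, cap
100 iterations), then back-transformation. Design choices:

* **Case/control is protected by default** (`protect_group = TRUE`): the
  group effect is a covariate during standardisation, so genuine disease
  signal is not absorbed into the batch correction. This requires the
  design not to confound group with batch, which is checked.
* **A single-batch matrix is a no-op**: with one batch the EB machinery is
  degenerate and there is nothing to remove.
* Shrinkage slightly perturbs per-gene grand means (order `1e-2` on
  realistic fixtures); this is a property of the reference algorithm, not
  an implementation artefact, and the test suite checks agreement with an
  independent implementation to below `1e-4` per cell.
* Only the parametric priors are implemented; adjustment is per cohort
  (each cohort's studies are its batches), never across the two diseases.

### Differential expression

Per gene, `fit_two_group()` computes `logFC = mean(case) − mean(control)`
(log2 scale) and the pooled two-sample variance with
`d_g = n₁ + n₂ − 2` degrees of freedom. `estimate_variance_prior()`
moment-matches `log s²_g` to the scaled-F model: the prior degrees of
freedom solve `trigamma(d₀/2) = var(log s²) − trigamma(d_g/2)` by Newton
inversion of the trigamma function, and `s₀²` follows from the mean of
`log s²` via the matching digamma terms; when the observed spread does not
exceed the sampling spread, `d₀ = ∞`. The moderated statistic shrinks each
variance toward the prior and is referred to a t-distribution with
`d₀ + d_g` degrees of freedom; p-values are two-sided, BH-adjusted.

Thresholds follow the reference analysis: FDR < 0.05 (exclusive) and
|logFC| ≥ 0.5 (inclusive — the boundary gene is called, a determinism
choice the thresholds' source leaves open). Shared DEGs are classified
co-up / co-down / inverse; the concordant fraction is reported because it
is exactly the quantity that makes naive direction inference ambiguous.

### The autoencoder and its conventions

The per-disease model (`autoencoder()`) is a symmetric dense stack
`n → 128 → 64 → 10 → 1 → 10 → 64 → 128 → n` (ReLU hidden layers, one-node
bottleneck, linear output), dropout 0.2 after every hidden layer except
the bottleneck and output, MSE reconstruction loss, Adam at learning rate
5e-4 (other optimiser constants at their conventional defaults: β₁ = 0.9,
β₂ = 0.999, ε = 1e-8), minibatches of 16. Where the architecture's source
is silent, this package decided:

* **Bottleneck activation is linear.** A ReLU bottleneck would clip half
  of the latent axis and make the score sign degenerate.
* **Decoder hidden activations mirror the encoder's ReLU.**
* **Inputs are per-gene z-scores computed from the training split only**,
  frozen and re-applied to any later sample; zero-variance genes get sd 1
  and a warning. Input scaling is otherwise unstated upstream.
* **Early stopping**: holdout MSE monitored each epoch, patience 10,
  minimum improvement `1e-4`, cap 500 epochs, best-epoch weights restored.
  The cap is far above what the synthetic cohorts need (typical best
  epochs are 20–60).
* **The 40% holdout doubles as the association test set.** The split is
  stratified 3:2 by case/control; the same held-out samples monitor early
  stopping and provide the evaluation cases. This mirrors the two-way
  split of the reference design, which uses "validation" and "test"
  interchangeably.
* **Sign canonicalisation.** An autoencoder's latent axis has no intrinsic
  sign: negating the bottleneck weights and the first decoder layer leaves
  the loss unchanged. Scores are therefore oriented so that training cases
  average at least training controls (`orientation ∈ {+1, −1}` stored with
  the model). Without this, the sign of any downstream correlation would
  be arbitrary; the test suite exercises the fact that flipping one
  encoder's orientation negates the cross-correlation.
* **Training is bit-reproducible** given the seed: initialisation (Glorot
  uniform), epoch shuffling and dropout masks all draw from one seeded R
  RNG stream, and inference never uses dropout.

`grid_search()` enumerates the reference hyperparameter grid — learning
rate {1e-4, 5e-4, 1e-3, 2e-3}, total dense depth {6, 8, 10}, first widths
{64, 96, 128}, second {32, 48, 64}, third {10, 12, 16}, dropout {0.1, 0.2,
0.3}; 972 combinations — training one model per combination with a shared
seed and returning the holdout-MSE minimiser (ties: first in enumeration
order). Depth 6 uses two encoder hidden layers; depth 10 inserts a fourth
hidden layer of 4 nodes (the source describes only the depth-8 model);
depth-6 combinations whose first two widths are not strictly decreasing
are enumerated but skipped as invalid. The default pipeline uses the
fixed reference configuration rather than re-searching.

### Cross-projection and the direction call

Held-out **cases** of each cohort (controls can be added with
`cases_only = FALSE` for sensitivity analysis — the association of
interest is between patients' severity axes) are scored under both
encoders; the opposite-disease score is counterfactual. `spearman_cor()`
uses average ranks, and a two-sided p-value from
`t = ρ √((n−2)/(1−ρ²))` with `n − 2` df; `|ρ| = 1` gives `p = 0`, and an
exact full-enumeration permutation p-value is available for `n ≤ 8`. A
constant score vector (a collapsed projection — possible when a network's
ReLU units all die on far-out-of-distribution counterfactual input) makes
the correlation undefined; the pipeline reports that evaluation as
indeterminate instead of failing.

Per cohort: positive if `ρ > 0, p < α`, inverse if `ρ < 0, p < α`, else
indeterminate (α = 0.05 by default; the reference analysis reports
p < 0.001 but states no threshold). The overall direction is the common
call of the non-indeterminate evaluations, and indeterminate on conflict
or when both are indeterminate.

### Enrichment and hub genes

`hypergeom_ora()` is a one-sided over-representation test,
`P(X ≥ k)` under the hypergeometric distribution, BH-adjusted, flagged at
FDR < 0.2. The universe defaults to the genes measured in the cohort under
test — the measured background is the correct sampling frame — and sets
with fewer than 3 members in the universe are skipped (a documented module
default; upstream tool defaults are unstated). Gene sets are consumed as
flat GMT sets; GO's graph structure is deliberately ignored.
`hub_genes_by_degree()` cleans the edge list (self-loops out, duplicates
collapsed keeping maximal confidence), drops edges below confidence 0.7
and returns the top 50 genes by degree, ties broken alphabetically.
The `"pathway_genes"` feature-set variant trains each disease's encoder on
the member genes of that cohort's significantly enriched sets instead of
the shared DEGs.

## The synthetic generator

`simulate_cohort_pair()` draws, for gene *g*, sample *i* of cohort *c*,

x\_gi = μ\_g + λ\_c,g · z\_i + γ\_g,b(i) + ε\_gi

with baseline μ\_g ~ N(7, 1) shared across cohorts (one platform), latent
severity z\_i ~ N(m·1[case], latent\_sd²), additive per-(gene, batch)
shifts γ ~ N(0, batch\_shift\_sd²) with round-robin batch assignment, and
Gaussian noise (an optional per-batch variance-inflation factor exercises
the scale half of batch adjustment). Shared dysregulated genes carry
loadings of magnitude `effect_sd` in both cohorts; a fraction
`frac_concordant` has the same sign in both, the rest opposite signs;
private dysregulated genes load in one cohort only. The planted truth
records all loadings and `true_sign = sign(Σ_g λ_A,g λ_B,g)` — the target
of direction recovery.

Default conditions (the study conditions of the package's own
validation): 2,000 genes, 200 shared + 2 × 100 private dysregulated
genes, loading magnitude 1.0 log2 units, case latent mean 1.0 with
within-group sd 0.5, 3 batches per cohort with shift sd 0.5, noise sd 0.5,
60 cases and 60 controls per cohort. The latent is continuous (cases
shifted, not constant) so that held-out case scores carry within-group
rank variation — a binary severity would make Spearman ranks degenerate.
Magnitude-0.5 noise and loading 1.0 put the median planted |logFC| near
1.0, comfortably callable at the 0.5 threshold with n = 120, which a
scientist would consider a realistic strong-signal microarray setting.

What the generator does **not** emulate: probe-level intensities,
heavy-tailed or heteroscedastic noise, gene–gene correlation beyond the
single latent factor, and platform annotation mismatches. Passing
sign-recovery tests therefore demonstrates the pipeline's logic and
numerics, not robustness to every pathology of real microarray
compendia — in particular, real data's multi-factor covariance could make
the one-dimensional bottleneck capture a nuisance axis.

## Numerical choices and degenerate inputs

* Probe collapsing keeps, per gene, the probe maximising |logFC|; ties
  keep the lexicographically smallest probe id (determinism).
* `s̃² = 0` in the moderated test: `t̃ = ±∞, p = 0` when `logFC ≠ 0`, and
  `t̃ = 0, p = 1` when `logFC = 0`.
* Trigamma inversion uses Newton iteration with asymptotic guards at both
  ends (`trigamma(x) ≈ 1/x²` small-x, `≈ 1/x` large-x), converging to
  relative `1e-12`.
* Constant genes standardise to zero; constant score vectors make the
  per-cohort call indeterminate (see above).
* All counts/fractions in configuration objects are validated on
  construction with errors naming the offending field.

## Problem sizes used by the validation suite

The test suite and the acceptance script size their simulations as: 10
simulated cohort pairs per planted direction at the default conditions
above for sign recovery; 10 seeds of 266-gene cohorts (25 cases/25
controls) for training-improvement checks; 10 seeds of 100-gene rank-1
cohorts (50/50) for latent-recovery checks; 2,000 genes for
variance-prior recovery; 20 effect-free pairs (2,000 genes, 30/30) for
the null-FDR check; and a 50-gene, two-batch, 300-sample fixture for the
planted-shift batch test (the residual batch-mean difference scales as
n^−1/2, so the fixture is sized to keep Monte-Carlo noise well below the
planted effect). Compact architectures (widths 32/16/4) are used where
the check concerns contracts rather than capacity.

## Known limitations

* The direction estimate is correlational; no causal or competing-risk
  interpretation is supported.
* One latent dimension cannot represent diseases whose shared
  transcriptomic response is genuinely multi-axis; a strongly mixed
  concordant/discordant structure can yield an honest `indeterminate`.
* Autoencoder training on very small cohorts (tens of samples) is noisy;
  the canonical-orientation rule uses training means and can flip when
  case and control score distributions heavily overlap.
* The EB batch adjustment assumes exchangeable gene-wise batch effects;
  study effects correlated with disease severity are not identifiable and
  will be partly retained (or removed) with the group covariate choice.
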