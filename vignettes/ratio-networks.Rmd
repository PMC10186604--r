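---
title: "Ratio-layer networks for metabolomic age: model, pipeline and validation"
author: "ratioAge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratio-layer networks for metabolomic age}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Untargeted LC-MS feature tables from routine screening labs are attractive
for aging research — tens of thousands of samples, thousands of features —
but they are experimentally hostile: hundreds of analytical batches, no
pooled QC samples to anchor drift correction, per-sample dilution
differences, and batch-wise missingness. Classical batch-correction methods
either need QCs or remove structure without improving downstream prediction.

The approach implemented here sidesteps explicit correction. A feed-forward
network first compresses the feature vector into a small number of linear
scores (default 12). Its second layer forms **all unique pairwise ratios**
of those scores — `12*(12-1)/2 = 66` outputs. If a sample-wide
multiplicative effect (dilution, injection volume, detector gain) scales
every feature, it scales every compression score equally, and the ratios
cancel it: the network self-normalizes. The ratio activations pass through
batch normalization and ReLU, then two 33-node hidden layers, then a single
output node that predicts age in years.

## The model in detail

Layer by layer (defaults; all configurable via `ratioNetConfig()`):

| layer        | operation                          | width | decay |
|--------------|------------------------------------|-------|-------|
| compression  | linear, no activation, no BN       | 12    | 0.5   |
| ratio        | all unique quotients, BN + ReLU    | 66    | none  |
| hidden 1     | linear, BN + ReLU                  | 33    | 0.1   |
| hidden 2     | linear, BN + ReLU                  | 33    | 0.01  |
| output       | linear                             | 1     | 0     |

Training uses Adam (learning rate `3e-4`) on shuffled minibatches of 500
samples with per-layer L2 weight decay and dropout 0.1 on every layer
*except* the ratio layer. We read "dropout on all layers except the ratio
layer" as dropout applied to the input features and to each hidden
activation, never to the ratio outputs or the compression scores feeding
them — dropping a denominator input would inject huge spurious ratios.

Numerical choices worth knowing:

* **Ratio stabilization.** Denominators are replaced by
  `sign(d) * max(|d|, ratio_epsilon)` with `ratio_epsilon = 1e-6`; zero
  denominators are treated as `+epsilon`. Within the clamp the gradient with
  respect to the denominator is zero. Setting `ratio_epsilon = 0` together
  with `use_bias = FALSE` makes the ratio activations *exactly* invariant to
  positive rescaling of the input (to floating-point rounding).
* **Batch normalization** is standard mini-batch activation normalization
  (biased variance, momentum 0.1); running statistics are frozen at
  prediction time. Offsets of a linear layer followed by BN are folded into
  the BN shift at evaluation.
* **Targets are standardized internally** (mean/SD of the training ages)
  and the affine transform is inverted at prediction. This changes the MSE
  objective only by a constant factor but keeps Adam well-conditioned at
  small epoch budgets.
* **Weight decay** acts on weight matrices only, never on offsets or BN
  scale/shift parameters; the 0.5 first-layer decay is harmless to the
  signal path because the ratio layer is invariant to the overall scale of
  the compression weights.
* **Checkpointing.** `final_epoch` is the default. With few minibatches per
  epoch the dev loss is visibly noisy ("unstable learning"), so the
  desk-scale experiments below use `checkpoint_policy = "best_dev"`: the dev
  partition is only ever evaluated, never differentiated, and the returned
  parameters are those of the best dev epoch.

Because single fits vary, the model is an **ensemble**: the architecture is
refitted `K` times from different seeds and the per-sample predictions are
averaged (the reference analysis used `K = 1000`; the desk default is 25,
which already captures most of the variance reduction — averaging can never
increase the expected squared error above the average member's). The spread
across members gives a per-sample standard error.

Predicted age is read as *biological age*. Since regression to the mean
under-predicts old and over-predicts young subjects, accelerated aging must
be scored against the mean prediction of one's age group
(`ageGroupBias()`), not against chronological age.

## Preprocessing

`fourthRoot()` compresses the intensity dynamic range; all rank-based
statistics are unaffected (the transform is strictly monotone).
`filterBatchMissingness()` drops features missing in strictly more than 20%
of the samples of *any* batch. `removePcaOutliers()` removes, in a single
pass, samples whose score on any of the first 12 principal components
deviates from the component median by more than 1.5 times the 95th
percentile of those absolute deviations; we read the published rule as a
threshold on deviations-from-median, and expose the alternative
quantile-of-scores reading behind `mode = "score"`. `selectRobustFeatures()`
keeps features whose median within-sample rank and max-min rank range both
lie inside the 20-80% quantile bands (inclusive; average ranks on ties, so
fully tied inputs keep every feature); `rowNormalize()` divides each sample
by its robust-subset sum, which cancels per-sample scaling exactly;
`quantileNormalize()` (via limma) equalizes distributions and is
idempotent. Missing values, where a learner needs completeness, are imputed
with per-(feature, batch) observed minima (`imputeMissing()`, half-minimum
optional) — the reference pipeline relied on upstream peak-filling and
never states a post-filter rule.

Order of operations follows the published narrative — fourth root, outlier
and missingness filters on that scale, robust selection and row
normalization on that scale too. The ratio network itself is trained on
fourth-root data *without* row or quantile normalization: in the published
screen those normalizations were only ever paired with the classical
learners, and the network's premise is that the ratio layer does the
normalizing. Rank-based robust selection is unaffected by the transform
order; the row-normalization divisors do differ between scales.

## The synthetic cohort generator

The study data cannot be shared, so validation runs on
`simulateCohort(syntheticSpec(...))`, which emulates the features of the
real cohort that matter to the method:

* **Ages** from a shifted log-normal, moment-matched to mean 28.9 y and SD
  9.2 y with skewness 1.5 (the reported distribution is right-skewed; the
  skewness value itself is our choice, solved for the log-normal shape),
  truncated to [15, 95].
* **Intensities** `I_ij = b_j * exp(beta_j z_i) * exp(eps_ij) * d_i *
  o_b(i)j`: log-normal feature baselines spanning decades
  (`baseline_log_sd = 1.2`), measurement noise `noise_sd = 0.3` on the log
  scale, per-sample log-normal dilution with CV `dilution_cv` (drawn last,
  so respecifying only the dilution rescales rows and nothing else),
  per-(feature, batch) multiplicative offsets with log-SD `batch_shift_sd =
  0.3` — at these defaults batch structure accounts for roughly the
  reported ~40% share of within-feature variance.
* **Planted signal**: `n_informative` features get a log-linear age effect
  whose sign mix is `inverse_fraction`; `beta` is calibrated analytically
  (through the Gaussian rank-correlation identity) so the noise-free
  Spearman correlation against age lands in `effect_size_range`, default
  0.3-0.6. The reported top univariate feature had rho = 0.26 with 8038
  features and ~10,000 samples; at desk scale (hundreds of features, ~1000
  samples) proportionally stronger planted effects keep the recovery
  problem comparable in difficulty. Chosen once, documented here.
* **Missingness** per (feature, batch) at a rate drawn from
  `missing_rate_range` (default 0-10%), missing at random, encoded as `NA`
  (never zero). The real missingness mechanism is unknown; MAR is the
  neutral choice.

What the generator does **not** emulate: retention-time drift at the peak
level, correlated metabolite modules, heteroscedastic noise, informative
missingness, or exogenous confounders (the cocaine-metabolite bias of the
real cohort). Passing recovery tests here shows the pipeline recovers
planted monotone signal under batch/dilution/missingness nuisance — not
that it would reproduce the biology of the original cohort.

## Validation experiments and their scale

The package validates itself end to end on generated cohorts (see
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`):

* **Recovery**: 1000 samples x 300 features, 20 batches, 20 planted
  mixed-sign features, dilution CV 0.3; 80/10/10 split; an ensemble of
  K = 25 networks trained 500 epochs on minibatches of 200 with best-dev
  checkpointing. We report the ensemble test RMSE against the
  constant-mean predictor, the fraction of planted features ranked in the
  SHAP top 40, and the sign agreement between attribution-intensity
  correlations and the planted signs. The batch size and epoch budget are
  scaled to the cohort (4 minibatches/epoch; the published regime used
  batches of 500 on ~8000 training samples for 1000 epochs, i.e. an order
  of magnitude more optimizer steps).
* **Attribution oracle**: exact-enumeration Shapley values on linear models
  match the closed form `w_i (x_i - mean(background_i))`; the
  permutation-walk estimator used above 12 features telescopes exactly, so
  additivity holds at machine precision for both.
* **Null safety**: on cohorts with no planted features, the realized false
  discovery proportion at BH q <= 0.01 stays below 5% over 20 replicates.
  One subtlety: per-sample dilution is a common mode shared by every
  feature, so feature-level Spearman p-values are *dependent*; marginal
  uniformity and FDP control hold, but a conditional KS uniformity check is
  only meaningful on a dilution-free null, which is how the unit test runs.

## A negative result: ratio vs matched dense network

A natural control is the architecture-matched plain dense network — the
identical stack with a learned 12 -> 66 linear layer in place of the ratio
operation. On the recovery cohort above (dilution CV 0.3, fourth-root
scale, matched budgets, five seeds) the dense control consistently reaches
a *lower* mean test RMSE than the ratio network; the same holds on the raw
intensity scale and in the exactly scale-invariant no-offset configuration.
The explanation is unglamorous: after the fourth root, dilution with CV 0.3
is ~7% relative noise — smaller than the measurement noise — and a dense
first layer can suppress a common mode to second order simply by learning
weights nearly orthogonal to the baseline direction, without paying the
ratio layer's optimization cost (near-zero denominators make its loss
surface rough). The corresponding acceptance check is therefore expected to
fail at these conditions, and we keep it failing rather than tilting the
generator: the ratio layer's value proposition lives in regimes this
desk-scale simulation does not reach — uncontrolled multi-year cohorts with
much stronger and more structured sample-scale artifacts, where the
published comparison was against normalization + classical learners, not
against a matched dense control.

## Tunable parameters that matter

* `effect_size_range`, `n_informative` — planted signal strength/extent;
  the single biggest driver of every recovery metric.
* `dilution_cv`, `batch_shift_sd` — nuisance strength (log scale).
* `epochs`, `batch_size` — the optimizer step count `epochs *
  ceiling(n/batch)` is what matters; at small n prefer smaller batches.
* `K` — ensemble size; returns diminish beyond ~25 at desk scale.
* `n_background`, `n_perm` (attribution) — estimator precision; additivity
  is exact regardless, only per-feature Monte Carlo noise shrinks with
  more walks.
* `ratio_epsilon` — trades exact scale cancellation against gradient
  spikes near zero denominators.

## Known limitations

* The permutation-walk Shapley estimator treats features as independent in
  the background marginal (interventional flavor); correlated features
  share credit accordingly.
* Training is plain R; it is deliberately vectorized and fast enough for
  cohorts of a few thousand samples, not for GPU-scale work.
* `screenModels()` treats its learners as black boxes with small internal
  tuning grids (5 candidates per dimension, 5-fold CV); it is a screening
  harness, not a benchmark.
* The exact-permutation Spearman p-value is enumerated only below n = 10;
  above that the t approximation is used (tie-corrected).
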