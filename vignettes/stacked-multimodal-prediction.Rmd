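---
title: "Stacked multimodal prediction with sparse principal component regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked multimodal prediction with sparse principal component regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Different brain measurements — resting-state functional connectivity,
cortical thickness, cortical surface area, subcortical volumes, local
white-matter connectome vectors — capture partly distinct properties of
neural architecture. Each modality alone is an extremely wide regression
problem (up to hundreds of thousands of features for around a thousand
subjects), and naively concatenating modalities makes the dimensionality
worse while mixing noise structures that differ across measurement types.

`stackpcr` implements a two-level *stacked generalization* scheme for this
setting. Each modality ("channel") is fit separately by a sparse principal
component regression; the channels' held-out predictions then become a tiny
meta-feature matrix (one column per channel) from which a second, non-negative
L1-penalized model learns which channels carry unique variance and how to
weight them. Redundant channels are shrunk to exactly zero; complementary
channels combine into a prediction that can exceed the best single modality.

## The level-1 estimator

For a channel matrix $X$ (subjects $\times$ features, centered by training
column means) we take the economy SVD $X = USV^{T}$, giving component scores
$Z = US$ and principal axes $V$. The response is regressed on the scores
under an L1 penalty,

$$\hat\beta = \arg\min_\beta \tfrac{1}{n}\lVert y - Z\beta\rVert^2
  + \lambda \lVert\beta\rVert_1,$$

and the coefficients are projected back to feature space as a weight map
$\hat w = V\hat\beta$, so prediction on new data is simply
$(X_{new} - \bar x)\hat w + \bar y$.

Implementation notes, all of which are deliberate choices:

* **Closed-form solve.** The columns of $Z$ are orthogonal
  ($Z^{T}Z = S^2$), so the penalized problem separates per component and is
  solved exactly by soft-thresholding —
  $\hat\beta_j = \mathrm{sign}(c_j)\max(0, |c_j| - n\lambda/2)/s_j^2$ with
  $c_j = z_j^{T}y_c$. There is no iterative solver at level 1, hence no
  convergence tolerance to document; the $\lambda \to 0$ limit is exactly
  the least-squares solution in the component space. The test suite
  cross-checks this solution against an independent penalized-regression
  solver (glmnet).
* **Objective scale.** The quadratic term is normalized by $n$, so
  duplicating every observation leaves the fit (and the meaning of
  $\lambda$) unchanged.
* **Components retained.** All $\min(n-1, p)$ components are kept — the L1
  step does the selecting, and truncating the basis would be a second,
  undocumented filter. The one exception is numerics: components with a
  singular value below $10^{-8}$ times the largest are genuinely null
  directions of the centered data and are dropped to avoid dividing by
  squared machine noise.
* **Scores are not standardized** before the L1 step, and features are
  centered but not variance-scaled before the SVD. The penalty therefore
  acts on the natural score scale, where high-variance components need less
  correlation with $y$ to survive. This is a convention, flagged here
  because reasonable pipelines differ on it.
* **Penalty selection.** $\lambda$ is chosen on a 30-point log-spaced grid
  from $\lambda_{max}$ (the smallest penalty that zeroes every coefficient,
  computed from the data as $2\max_j |c_j|/n$) down to
  $10^{-3}\lambda_{max}$, by inner $k$-fold (default 5) cross-validation
  minimizing mean squared error. The plain minimum-MSE rule is used, not
  the one-standard-error rule. Ties (flat CV curves) resolve to the larger
  penalty because the grid is scanned in decreasing order.
* **Prevalidation.** The same inner folds that select $\lambda$ produce the
  out-of-fold training predictions used as meta-features: each fold's rows
  are predicted by a model (PCA refit included) that never saw them. The
  final channel model is then refit on all training rows at the selected
  penalty.

## The level-2 model

Out-of-fold predictions are stacked into an $n \times K$ matrix $M$ (one
column per channel) and the meta-model solves

$$\min_{b \ge 0} \tfrac{1}{n}\lVert y - a - Mb\rVert^2 + \lambda \sum_k b_k.$$

The non-negativity constraint keeps the surviving weights interpretable as
channel contributions; the L1 term removes redundant channels exactly.
Choices here:

* Meta-features enter uncentered and unscaled — they already share the
  response's units — and an unpenalized intercept is included (the model
  predicts a centered response; whether the original procedure carried an
  intercept at this level is not documented, so we opted for the safer
  choice).
* The solver is cyclic coordinate descent over at most a handful of
  columns, converged to a $10^{-12}$ relative tolerance, warm-started along
  the same 30-point decreasing grid construction as level 1 (with
  $\lambda_{max}$ from the positive-part correlations, since only
  non-negative coefficients can enter). Coefficients below $10^{-9}$
  (relative to the largest) are reported as exact zeros; with exactly
  duplicated columns the fixed cyclic order makes the first copy absorb the
  signal and the later copies stay at zero. Duplicate-column behaviour is
  tested at the level of predictions, which are unique even where the
  coefficient split is not.
* The confounder channel, when enabled, enters this stage exactly like an
  imaging channel.

## Evaluation protocol

Generalization is measured by Monte Carlo cross-validation: by default 100
random 70/30 train/test partitions in which every *family group* (twin
pair) is kept wholly on one side, because twins' correlated traits would
otherwise leak across the split and inflate accuracy. Groups are shuffled
and accumulated into the test side until its size is nearest
`round(0.3 n)`; the realized size is always within one group of the
target. An optional stratified variant allocates groups within quintile
bins of the group-mean response; it is off by default, matching the plain
group-shuffle description of the protocol (the stratified reading is
exposed as a flag).

Per split we record $R^2$ and MAE for each channel and for the stacked
model, the channel meta-coefficients, and the *stacking bonus*
$B = R^2_{stacking} - R^2_{best}$ (conservative form; the mean-referenced
form $R^2_{stacking} - \langle R^2\rangle_{single}$ is also computed).
Medians over splits are summarized with percentile-bootstrap confidence
intervals (1000 resamples, $\alpha = 0.05$; R's default sample-quantile
definition). Medians suit the sparse level-2 coefficients, whose per-split
distribution has a point mass at zero. Channels are compared with a paired
one-tailed Wilcoxon signed-rank test plus the matched-pairs rank-biserial
correlation $(T^+ - T^-)/(T^+ + T^-)$; zero differences are dropped, and an
all-zero comparison is reported as $p = 1$ with a warning rather than an
error.

## Confound handling

Two mechanisms, for two kinds of confounder:

* **Intracranial volume** affects both brain features and cognition; its
  linear effect is removed from the *response* by a regression whose
  intercept and slope are estimated on the training set only and then
  applied to both sides of the split. Training residuals are exactly
  orthogonal to the training confounder; test responses never touch the
  fit.
* **Demographic mediators** (age, sex, education) form an additional
  channel (`confounder_channel()`: age as-is, one sex indicator with the
  reference level dropped, education as a numeric ordinal — the original
  coding is not documented, so the simplest full-rank coding is used). If
  demographics explain the response, the level-2 model shrinks the imaging
  channels away, which quantifies how much imaging predicts *beyond*
  demographics.

## The synthetic cohort generator

Real multimodal cohorts with family structure are access-restricted, so the
package ships a generator whose ground truth is known. It emulates exactly
the statistical structure the analysis assumes: a shared latent trait
expressed in several channels, channel-unique signal components, twin pairs
with correlated traits, sparse generative loadings (10% nonzero by
default), a volume confounder that can shift both features and response,
and demographic mediators. The response's variance decomposes as configured
(shared share = mean of the per-channel shared fractions; one unique share
per channel; confounder contributions add on top of the unit-variance
core); twins' traits are drawn from a bivariate normal, the simplest
exchangeable-pair construction.

What it does **not** emulate: spatial covariance within a modality beyond
the rank-one signal structure, non-Gaussian feature distributions, site or
motion artifacts, heteroscedastic noise across features, and any
calibration to a real cohort's covariance (no public reference data exist
for that). Passing tests on this generator therefore demonstrate
correctness of the machinery and qualitative behaviour (complementarity
helps, redundancy is removed, nulls stay null) — not expected effect sizes
on real data, which are far smaller than in these clean simulations.

Defaults were chosen once as plausible for the field: cohorts of 400
subjects, 40% of subjects in twin pairs with trait correlation 0.5, unit
feature noise. The simulation studies used in the tests and in
`scripts/acceptance.R` run at n = 400 with channels of 100–150 features and
50 Monte Carlo splits — sizes at which a full study completes in seconds
while the Monte Carlo intervals are already narrow.

## A known property: the recalibration bonus

Cross-validated L1 models shrink: their predictions are systematically
attenuated toward the training mean, slightly more so because the penalty
is tuned on folds smaller than the final training set. The level-2
regression learns a slope on those predictions and therefore *undoes* part
of the attenuation — on the fully-redundant simulation (one informative
channel duplicated exactly) the surviving channel's meta-coefficient is
about 1.2 and the stacked model beats the raw single channel by a small
but systematic margin (median bonus $\approx 0.008\ R^2$ at the simulation
conditions above). A duplicated channel's own coefficient is exactly zero,
so redundancy *is* removed; but the bonus statistic conflates genuine
cross-channel complementarity with this single-channel recalibration gain.
Interpret small positive bonuses (of order 0.01) with that in mind; the
complementary-signal bonus in the same conditions is an order of magnitude
larger.

## Degenerate inputs and edge behaviour

* Zero-variance features are dropped per channel using training rows only,
  with labels reported (`drop_zero_variance()`); an all-constant channel is
  an error.
* A zero-variance confounder triggers an intercept-only adjustment with a
  warning.
* $R^2$ against a zero-variance evaluation response is an error, not a
  `NaN`.
* `maxabs_rescale()` returns all-zero input unchanged; zeros stay exactly
  zero so sparsity is never broken.
* `strength_map()` keeps `ceiling(top_fraction * n_links)` links; ties at
  the threshold value are all kept. The thresholding is applied to the
  link weights *before* row summation — reading the per-region strength as
  a sum over a region's surviving links.
* Full-data refits for interpretation (`refit_full()`) re-optimize the
  penalty by inner CV rather than reusing a split-specific value (the
  original choice is undocumented; re-optimization is the self-consistent
  reading). Only channels whose median meta-coefficient bootstrap interval
  excludes zero are refit; encoding patterns $A = \Sigma_X \hat w$ omit the
  scalar response-variance factor and are reported max-abs rescaled, so
  maps are interpretable up to a positive scale. The covariance uses the
  $n-1$ denominator (irrelevant after rescaling, recorded for
  completeness), and is applied implicitly as $X_c^{T}(X_c \hat w)/(n-1)$
  so the $p \times p$ matrix is never materialized.

## Limitations

* No elastic-net or ridge variants, no classification mode, no
  random-forest meta-learner, and no multi-response stacking.
* Residualization handles a single neuroimaging confounder; several would
  require sequential or multiple regression, not implemented.
* The generator's defaults are not calibrated to any real cohort's
  covariance structure; absolute performance numbers from simulations do
  not transfer to real data.
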