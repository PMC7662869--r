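---
title: "Methods: behavioral dimensions of substance-use vulnerability and their connectome-based prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral dimensions and connectome-based prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmrisk)
```

## The analysis in two stages

`cpmrisk` implements a pipeline for studying vulnerability to substance use in
children before any use begins. It has two stages.

**Stage one (behavior).** Substance-related questionnaire batteries in child
cohorts are heavily right-skewed: as item severity increases, ever fewer
participants endorse it, so most items are zero-inflated counts or rare
binaries. Each item is therefore normalized with the Yeo-Johnson power
transform, whose parameter $\lambda$ is estimated per item by maximum
likelihood, and standardized to mean 0, sd 1. The standardized matrix is
reduced by PCA (singular value decomposition); the retained rank is chosen by
Bayesian model selection — the Laplace approximation to the model evidence of
probabilistic PCA evaluated at every candidate rank. Loading reliability is
assessed with a subject-level percentile bootstrap: a loading is *reliable*
when its 95% interval excludes zero. The first component typically captures a
risk-seeking dimension (curiosity, intention, early sips) and the second a
familial dimension (family history, household smoking); subjects are scored by
projecting their normalized responses onto the loadings.

**Stage two (prediction).** Functional connectomes — node-by-node matrices of
Fisher-z-transformed Pearson correlations between parcel time courses — are
vectorized into edge vectors (a 268-node parcellation gives
$268 \cdot 267/2 = 35{,}778$ edges) and used to predict the component scores
with ridge regression under 10-fold cross-validation. On each fold, edges are
z-scored with training-set parameters only; the ridge penalty $\alpha$ is
tuned by a second, inner 10-fold cross-validation within the training sample;
the fitted model predicts the held-out subjects. Performance is the partial
correlation $r_p$ between predicted and observed scores, adjusting for head
motion (mean frame-to-frame displacement, mean rotation, maximum displacement)
and the number of retained frames, with a percentile bootstrap confidence
interval. Conditions (rest and tasks) can be combined by concatenating edge
vectors; univariate feature selection within each training fold can equalize
the feature count against a single condition.

## Model and assumptions

The prediction model is linear:
$$\hat y = \bar y_{\text{train}} + X_z \beta, \qquad
\beta = (X_z^\top X_z + \alpha I)^{-1} X_z^\top (y - \bar y_{\text{train}}),$$
with $X_z$ the train-standardized edge matrix and the intercept unpenalized.
For $p \gg n$ the coefficients are computed through the exact dual identity
$\beta = X_z^\top (X_z X_z^\top + \alpha I)^{-1}(y - \bar y)$, which reduces
every solve to the $n \times n$ Gram matrix. The statistical assumptions are
the usual ones for CPM-style analyses: an approximately linear edge-score
relationship, exchangeable subjects (no family/site structure — see
Limitations), and covariates that enter linearly in the partial correlation.

The behavioral stage assumes that after a monotone power transform the items
are close enough to Gaussian for PCA and the probabilistic-PCA evidence to be
meaningful. The transform is fitted once on the full behavioral sample;
refitting on a subset (to keep the behavioral loadings statistically
independent of an imaging subsample) is supported by simply calling
`fitComponentModel()` on the subset and comparing with `loadingSimilarity()`.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| QC thresholds | 0.15 / 2 / 3 | mm, mm, degrees | runs are excluded when mean frame-to-frame displacement, maximum displacement or maximum rotation *strictly exceeds* its threshold ("more than"); values exactly at threshold pass |
| smoothing `sigma` | 1.95 | frames | Gaussian temporal filter; at a 0.8 s repetition time this is an approximate 0.12 Hz cutoff |
| drift order | 3 | — | linear, quadratic, cubic orthogonal polynomials |
| motion regressors | 24 | — | 6 base parameters, their one-frame backward differences (first frame 0), and squares of both |
| correlation clip | $1 - 10^{-7}$ | — | keeps the Fisher z transform finite for numerically perfect correlations |
| `alphaGrid` | $10^{-3} \ldots 10^{5}$, 13 log-spaced values | — | spans near-OLS to near-constant predictions; ties break toward the smaller penalty |
| folds (outer, inner) | 10, 10 | — | unstratified uniform random assignment, sizes within one, mandatory seed |
| `nBoot` | 10,000 (performance), study-sized elsewhere | — | percentile 2.5/97.5 intervals |
| top-edge `fraction` | 0.001 | — | round-half-away-from-zero of `fraction * nEdges`; 0.1% of 35,778 edges is 36 |

The inner tuning loop scores each candidate $\alpha$ by the mean inner-fold
Pearson correlation between inner-held-out predictions and observations — the
convention in connectome-based prediction. The inner loop operates on the
matrix as standardized by the *outer* training fold; standardization
parameters never see outer test subjects.

## What the synthetic-data generator emulates

The generator plants known ground truth so every stage can be tested for
recovery and calibration:

* **Items** (`generateItemResponses()`): latent factor scores
  $F \sim N(0, \Sigma_f)$, item latents $F L^\top + \varepsilon$ with noise
  variance $\max(1 - \mathrm{Var}(FL^\top_j),\ 0.05)$, so with
  `skewSeverity = 0` the item-factor correlation equals the loading exactly.
  With severity $s > 0$ the response is the monotone zero-inflated count
  $\lfloor e^{(z - s)} - 1 \rceil$ for $z > s$ and 0 otherwise, reproducing
  the "fewer endorsements as severity increases" shape; skewness increases
  with $s$. The default two-block specification
  (`twoBlockFactorSpec()`) mirrors a risk-seeking block and a familial block
  on orthogonal factors.
* **Connectomes** (`generateConnectomes()`): each signal edge is
  $r z + \sqrt{1 - r^2}\,\epsilon$ (times a noise scale), so the population
  edge-score correlation is exactly the requested effect size; all other
  edges are pure noise.
* **Time series** (`generateTimeseries()`): frames drawn through the Cholesky
  factor of a target correlation matrix, plus separable drift, motion-like
  random-walk and smooth tissue-like confound signals returned as a regressor
  matrix.
* **Motion** (`generateMotion()`): log-normal summaries. When a confound
  strength $s$ is requested, the latent normal correlation is set to
  $s\sqrt{e^{\sigma^2} - 1}/\sigma$, which makes the *observed* log-normal
  mean FFD correlate with the scores at exactly $s$ (Stein's lemma). The
  default is $s = 0$: motion uncorrelated with behavior.

What it does **not** emulate: scanner physics, task timing, realistic fMRI
noise spectra or autocorrelation, mixed ordinal/binary item formats beyond
zero-inflated counts, site effects, or family structure. Passing tests on
this generator demonstrate that the estimators recover what they claim under
their own assumptions — not that real acquisition artifacts are handled.

## Numerical choices

* **$\lambda$ estimation**: profile log-likelihood maximized on $[-5, 5]$ by a
  coarse 41-point bracket followed by derivative-free refinement
  (`stats::optimize`); verified in tests against a 0.01-step grid search and
  an established power-transform fitter. The transform itself is computed via
  `expm1`/`log1p`, so it is numerically continuous in $\lambda$ at 0 and 2.
* **PCA sign convention**: every loading column is flipped so its
  largest-magnitude element is positive (first such element on ties), making
  results deterministic across platforms. Rank-deficient input warns and
  truncates at the numerical rank (relative threshold $10^{-9}$).
* **Component alignment** (bootstrap replicates, split-half comparisons):
  greedy assignment on the absolute correlation between loading columns, ties
  broken by component index, then a sign flip to positive correlation.
* **Evidence computation**: candidate ranks $1..\min(n-1, p-1)$; tail
  eigenvalues floored at $10^{-15}$; smallest rank wins ties.
* **Ridge**: primal solve when $p \le n$, dual (Gram) solve otherwise;
  eigenvalues below `max(d) * 1e-12` are treated as zero, so $\alpha = 0$
  yields the minimum-norm solution. `permutationNull()` shares the per-fold
  standardization, Gram matrices and inner-fold eigendecompositions across
  permutations — these depend only on the features and the fold split —
  while alpha tuning and fitting rerun per permutation; folds are held fixed
  across permutations, which is valid under the exchangeability of the null.
* **Degenerate guards**: constant items are dropped with a message; constant
  edge columns standardize to zero and get univariate correlation 0 (never
  selected ahead of any informative edge); bootstrap resamples that collapse
  an item to zero variance are redrawn and counted; resamples with degenerate
  residuals in the performance bootstrap are skipped, and more than 50%
  degenerate is an error.
* **Aggregation across runs**: entrywise mean on the Fisher-z scale (the
  variance-stabilized scale on which averaging is conventional). Averaging,
  rather than concatenating time series, is the implemented choice for
  multiple rest runs and the two runs of a task.

## Design choices where the design was open

* `sigma` is in frames; the stated cutoff frequency matches frames at the
  acquisition's repetition time.
* Transform-then-standardize (rather than folding standardization into the
  transform): the fitted parameters record the post-transform mean and sd.
* All retained components are exposed; reporting defaults to the first two,
  which carry the interpretable dimensions.
* Univariate feature selection ranks by *absolute* correlation and runs
  inside each training fold, before standardization of the selected columns.
* The single-condition covariate set is mean FFD, mean rotation, maximum
  displacement and frame count; the combined model averages mean FFD, maximum
  displacement and maximum rotation across conditions and totals the frames.
  Both sets are assembled by `motionCovariates()` and are configurable,
  because the two published lists differ and neither is guessed as intent.
* Percentile (not BCa) bootstrap intervals throughout — the simplest method
  consistent with reporting 95% intervals over bootstrap resamples.
* Cross-condition model comparison uses the mean of per-fold coefficient
  vectors; the distinctiveness interval resamples *edges* with replacement
  (`distinctivenessCI()`), an explicit interpretation since subject-level
  resampling is unavailable at the coefficient level.

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to balance statistical
resolution against a single-CPU run: null calibration with 100 permutations
at $n = 300$ with 1,000 edges; signal recovery at the full published feature
scale ($n = 500$, 35,778 edges, 300 planted edges at effect size 0.3);
bootstrap coverage with 200 replicates of 500-resample intervals, with the
loading-coverage study at $n = 2{,}000$ subjects — comparable to the scale at
which the behavioral analysis operates and inside the asymptotic regime where
percentile intervals attain their nominal level. The acceptance script
(`scripts/acceptance.R`) recomputes the same quantities from scratch under a
caller-supplied seed.

## Known limitations

* **CV correlation is not exactly centered under the null.** Pooled
  out-of-fold correlation has a small negative bias when predictions shrink
  toward the training-fold mean: the fold means anti-correlate with held-out
  outcomes (a pure fold-mean predictor yields $r = -1/\sqrt{n_{\text{fold}}}
  \approx -0.18$ at these sizes). With inner tuning on permuted outcomes,
  heavy-shrinkage penalties are sometimes selected, so the permutation null
  averages a few hundredths below zero rather than exactly zero. This is a
  property of the estimator, not leakage (which would bias positively, and is
  excluded by a bitwise invariance test). It is exactly why observed
  performance should be compared against the *permutation null distribution*
  — as `permutationNull()` does — rather than against zero.
* **Percentile bootstrap coverage is asymptotic.** Loading intervals
  undercover at small $n$ (we measure ≈0.83 at $n = 300$, ≈0.96 at
  $n = 2{,}000$ for the two-block model); interpret reliability flags from
  small samples cautiously.
* The evidence-based rank selection assumes isotropic residual noise;
  strongly heteroscedastic items can shift the selected rank.
* No site, family-structure or demographic covariates are modeled; subject
  exclusions (e.g. siblings) are the caller's responsibility via the supplied
  subject list.
* PCA on power-transformed items is a pragmatic choice for mixed-type data;
  polychoric-correlation approaches may suit ordinal items better.
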