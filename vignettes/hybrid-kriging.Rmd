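---
title: "Hybrid machine-learning residual kriging: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid machine-learning residual kriging: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mlkrige)
```

## The prediction problem

`mlkrige` predicts a continuous response observed at scattered planar
locations — the motivating case is log invasive-plant cover on forest
inventory plots — from two complementary sources of structure:

1. a **trend**: the part of the response explained by covariates measured at
   each location (climate, stand structure, soil, diversity, ...), and
2. **residual spatial autocorrelation**: whatever the covariates miss but
   nearby locations share.

Machine-learning regressions capture the first and assume independent
errors; ordinary kriging captures the second and assumes a constant mean.
The hybrid estimators combine them additively:

$$\hat y(x_0) \;=\; \hat m(x_0) \;+\; \hat e(x_0),
\qquad \hat e(x_0) = \sum_{i} \lambda_i \, e(x_i),$$

where $\hat m$ is a fitted trend model, $e(x_i)$ are its training residuals
(observed minus fitted), and the $\lambda_i$ are ordinary-kriging weights
determined by the residual spatial-dependence structure. With a
boosted-regression-tree trend this is **BRTOK**; with a LASSO trend,
**LASOK**. Fitting is a three-step procedure (`fit_hybrid()`): fit the
trend, krige its residuals, sum.

## Components and their assumptions

### Ordinary kriging (`krige_point`, `krige_grid`)

The predictor at $x_0$ is the weighted sum of the $k = \min(n_{max}, n)$
nearest observations, with weights solving the standard
$(k{+}1)\times(k{+}1)$ system with a Lagrange multiplier and the
unbiasedness constraint $\sum_i \lambda_i = 1$. Assumptions: the field has
a locally constant (unknown) mean and a stationary isotropic semivariogram.
We do **not** assume the residual field has mean zero globally — the
constant-mean assumption applies within each search neighborhood.

The search window `nMax` is purely count-based (no radius cap or minimum
distance rule): it is the single kriging tuning parameter, typically
searched over 10–150. Small `nMax` tracks short-range structure and is
cheap; large `nMax` approaches global kriging.

### Semivariogram estimation (`empirical_variogram`, `fit_spherical`)

The Matheron method-of-moments estimator over distance bins:
$\hat\gamma(h_b) = \frac{1}{2|N(h_b)|}\sum_{(i,j)\in N(h_b)} (y_i-y_j)^2$.
Defaults: 15 equal-width bins, cutoff at one third of the maximum pairwise
distance — the convention of the standard geostatistics toolchain; both are
configurable. Zero-distance pairs are excluded (the semivariogram is
defined for $h > 0$), and empty bins are dropped; each bin reports the mean
separation of its pairs.

Only the spherical model is fitted:
$\gamma(h) = c_0 + c_1\,(1.5\,h/a - 0.5\,(h/a)^3)$ for $0 < h \le a$, flat
at the sill $c_0 + c_1$ beyond the range $a$, and $\gamma(0)=0$ by
convention. The fit is weighted least squares with weights $N_b / h_b^2$
(pair counts over squared lag — the common software default, emphasising
well-estimated short lags). Because the model is linear in $(c_0, c_1)$
given $a$, those two are profiled out in closed form (with nonnegativity
enforced by case analysis) and the range is found on a deterministic
log-spaced candidate grid refined by golden-section search. This avoids
both optimizer seeds and the multimodality traps of joint 3-parameter
minimisation. A flat empirical variogram resolves deterministically to a
pure-nugget fit with the range at the lower search bound.

### Boosted regression trees (`fit_brt`)

Gradient boosting for squared-error loss: start from the response mean;
at each iteration fit a depth-limited regression tree (exhaustive best-SSE
split search) to the current residuals on a random `bag_fraction`
subsample, and add it scaled by the learning rate. Defaults mirror the
common boosting toolchain: `learning_rate = 0.1`, `max_depth = 1`
(additive stumps), `bag_fraction = 0.5`, `min_obs = 10` per leaf. Only
`n_trees` (100–800) is treated as the tuning parameter in evaluation; the
others are exposed but fixed. One integer seed drives all bagging draws
(through R's RNG), so a fitted ensemble is exactly reproducible; the
sensitivity of results to the non-tuned settings is a known open point and
is deliberately left to the user.

### LASSO (`fit_lasso`)

Cyclic coordinate descent with soft-thresholding for
$$\hat\beta_\lambda = \arg\min_{\beta_0,\beta}\;
  \tfrac1N \sum_i (y_i - \beta_0 - x_i^T\beta)^2 + \lambda\|\beta\|_1 .$$
Note the scale: $\tfrac1N$ on the RSS and no $\tfrac12$. The 0.01–1 search
grid for $\lambda$ is interpreted on exactly this scale; solvers using
$\tfrac1{2N}$ (e.g. glmnet) reproduce the fit at $\lambda/2$. The
intercept is unpenalized. Convergence: maximum absolute coefficient change
below `tol = 1e-7` per sweep, hard cap `max_iter = 1e5` sweeps (an error,
carrying the last change norm, if exceeded). `lasso_lambda_max()` computes
the smallest all-zero penalty with the same floating-point arithmetic as
the coordinate update, so "at or above `lambda_max`" yields exact zeros.

Covariates should be standardized before LASSO fitting (see below): the
penalty then acts uniformly and coefficient magnitudes are comparable,
which is also the convention used to rank selected variables in
`lasso_selection()` — the selected set is exactly the nonzero-coefficient
set; magnitudes are a documented convention on top, since penalized
selection itself carries no canonical importance score.

## Preprocessing

`preprocess_fit()` standardizes covariates to mean 0 / unit variance and
optionally replaces the response by $\log(y + \text{offset})$. The offset
defaults to 1 (log1p-style) because cover-type responses legitimately
contain zeros; it is recorded and invertible. Zero-variance covariates are
an error, named.

Two standardization modes exist in cross-validation: `"global"` (the
default) standardizes once on the full dataset before splitting —
mirroring the common practice of pre-standardized ecological layers — and
`"per_fold"` refits the statistics on each training fold, which is the
leakage-free variant. The difference is negligible for well-behaved
covariates but the switch makes the choice explicit.

**All model fitting and evaluation happens on the transformed (log)
response scale; RMSEs are reported on that scale and never
back-transformed.** Back-transform bias corrections (lognormal kriging) are
out of scope.

## Evaluation protocol

`cross_validate()` runs k-fold CV (default $k = 10$): per fold, the full
pipeline is refitted on the training folds — including the residual
variogram for hybrids, and the response variogram for plain OK — and the
held-out points are predicted. The pooled RMSE is computed over the
concatenation of all held-out predictions (and is asserted in the tests to
equal that monolithic recomputation).

`grid_search()` tunes `nMax` (OK), `n_trees` (BRT), `nMax × n_trees`
(BRTOK) or `nMax × lambda` (LASOK) by pooled CV-RMSE on one shared fold
partition. Default grid steps are 5 (nMax), 50 (nTrees) and 0.005
(lambda) over the standard ranges; ties resolve to the smaller `nMax`,
then the smaller second parameter.

`repeated_cv()` repeats the protocol (default 100 times); repeat $r$ uses
fold seed `seed + r - 1`, and **all algorithms share the identical
partition within a repeat** — the pairing that `paired_ttest()` (classical
two-sided paired t, $R-1$ df) requires. Parameters are fixed before
repeating rather than re-tuned inside each repeat; re-tuning can be
composed manually from `grid_search()` if wanted, but at two orders of
magnitude more compute.

The training-size guard: hybrid fits require $n > 2p + 20$
(`min_train_size()`), the standard rule of thumb for the smallest sample
supporting a $p$-covariate regression. Violation is an error by default
and a warning with `enforce_guard = FALSE`; the guard encodes the
empirical observation that below this size the hybrids have no reliable
advantage over plain OK.

## The synthetic generator: what it emulates, and what not

`make_dataset()` draws locations uniformly on the unit square, covariates
i.i.d. standard normal (optionally correlated through one latent factor to
emulate ecological multicollinearity), and composes the response as
`trend(X) + GRF + white noise`. The Gaussian random field uses the
spherical covariance $C(h) = (c_0+c_1) - \gamma(h)$ via dense Cholesky
(diagonal jitter `1e-10` only if needed, recorded), which caps practical
sizes at a few thousand points — ample for desk-scale testing, not for
survey-scale data. The nonlinear trend is additive smooth terms (sine,
centered quadratic, tanh) plus one pairwise interaction, so tree ensembles
hold a genuine advantage over linear fits on that spec.

Two named benchmarks fix the study conditions used throughout the tests
and the acceptance script:

* `benchmark_spec()` — $n = 800$, $p = 10$, three active covariates
  (nonlinear + interaction, unit effects), residual field
  $(c_0, c_1, a) = (0.1, 0.5, 0.3)$, noise sd 0.2. The residual range
  (0.3) is large against the typical nearest-neighbor spacing
  ($\approx 0.02$), so residual kriging has real signal: the regime where
  BRTOK should beat BRT and both hybrids should beat OK.
* `small_n_spec()` — $n = 90$, $p = 39$ (violating $2p+20 = 98$), with a
  deliberately weak and diffuse trend: ten active covariates at effect 0.1
  each ($\approx 1\%$ of response variance apiece), residual field
  dominant. At 81 training points no learner can separate that signal
  from overfitting noise, which is precisely the small-sample regime where
  plain OK is the right tool. An earlier draft with three moderately
  strong effects made the trend learnable and the hybrid won — i.e. it
  failed to represent the intended regime, which is why the weak-diffuse
  form is the committed default.

What the generator does **not** emulate: real survey sampling geometry or
regional stratification, anisotropy or nonstationarity, non-Gaussian
responses, covariates with spatial structure of their own. Passing the
simulation suite therefore demonstrates correctness of the estimators and
the claimed qualitative orderings *under the assumed model*, not
performance guarantees on any particular field dataset.

## Numerical choices worth knowing

* **Kriging solve conditioning**: the kriging system is solved on a
  sill-normalized scale ($\gamma / (c_0+c_1)$) — weights are invariant to
  rescaling $\gamma$, and this keeps the system well-conditioned even for
  near-zero residual fields (e.g. an almost perfect trend); the variance
  is scaled back. Variances in $[-10^{-8}, 0)$ are clamped to 0; anything
  more negative is an error.
* **Neighbor ties**: equidistant neighbors are ordered by ascending row
  index (stable radix order) for determinism.
* **Duplicate locations**: duplicated training coordinates make the
  kriging system singular and are rejected with the offending row indices;
  `dedup_average()` provides the averaging preprocessor for data where
  duplicates are legitimate.
* **Distances** are plain Euclidean on the coordinate columns, including
  latitude/longitude treated as planar degrees — adequate at regional
  extents and consistent with common practice; no great-circle option is
  provided.
* **`krige_grid` vs `krige_point`**: the grid version calls the identical
  single-point core, so the two are bitwise equal by construction, as is
  the hybrid additivity `predict_hybrid = predict_trend + krige_grid`.

## Limitations

Beyond the generator caveats above: no universal/co-kriging, no
non-spherical variogram families, no spatially blocked CV (folds are
plain random, as is standard for this protocol), no uncertainty for the
trend component (the exposed variance is the residual-kriging variance
only), and no raster output — predictions are returned at explicit target
coordinates. When BRTOK and LASOK disagree, the package takes no position:
run both and choose by cross-validated RMSE.
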