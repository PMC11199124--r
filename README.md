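# mlkrige

Hybrid machine-learning residual kriging for point-referenced spatial
prediction.

Ecological responses such as invasive-plant cover on inventory plots carry
two kinds of structure at once: a covariate-driven trend (climate, stand
structure, soil, diversity) and residual spatial autocorrelation that the
covariates miss. Pure machine-learning regressions exploit the first and
ignore the second; ordinary kriging does the opposite. `mlkrige`
implements the additive hybrids that use both:

    ŷ(x₀) = m̂(x₀) + ê(x₀),   ê(x₀) = Σᵢ λᵢ e(xᵢ)

where `m̂` is a machine-learning trend — boosted regression trees
(**BRTOK**) or the LASSO (**LASOK**) — `e(xᵢ)` are its training residuals,
and the weights `λᵢ` (summing to one) solve the ordinary-kriging system
built from a spherical semivariogram fitted to those residuals over the
`nMax` nearest neighbors. The package is aimed at spatial ecologists and
geostatisticians who want the hybrid estimators, their OK and BRT
baselines, and the full evaluation protocol — k-fold cross-validation with
grid search, 100-repeat CV with shared folds, paired t-tests — plus
variable-importance ranking (BRT relative influence, LASSO selection) and
a synthetic generator with known truth for testing, all in one place.

Everything methodological is in-package and documented: Matheron
semivariogram estimation with weighted-least-squares spherical fitting,
local-neighborhood kriging with prediction variance, exhaustive-split
gradient boosting (tree growing in C++), cyclic coordinate-descent LASSO
on the `(1/N)·RSS + λ‖β‖₁` objective scale, the `n > 2p + 20`
training-size guard for hybrid fits, and the preprocessing conventions
(covariate standardization, log response transform). See the methods
vignette (`vignettes/hybrid-kriging.Rmd`) for models, assumptions,
defaults and limitations.

## Worked example

Simulate a dataset with a nonlinear covariate trend plus a spatially
structured residual field, fit BRTOK, and compare it against plain OK by
repeated cross-validation on shared folds:

```r
library(mlkrige)
sim <- make_dataset(sim_spec(n = 400, p = 6, trend = "nonlinear-interaction",
                             active = 1:3, effects = c(1, 1, 1),
                             residual_vm = variogram_model(0.1, 0.5, 0.3),
                             noise_sd = 0.2, seed = 1))
d <- sim$data

m <- fit_hybrid(d, "brt", brt_config(n_trees = 200, seed = 1), nMax = 30)
m
#> <hybrid_model> trend: brt + residual ordinary kriging (nMax 30)
#> <variogram_model> spherical: nugget 0.443969, psill 0.782101, range 0.382154 (sill 1.22607)

rcv <- repeated_cv(d, list(ok = list(nMax = 30),
                           brtok = list(nMax = 30,
                                        brt = brt_config(n_trees = 200, seed = 1))),
                   repeats = 5, k = 10, seed = 1)
rcv
#> <repeated_cv> 5 repeats of 10-fold CV
#>           ok   brtok
#> mean 1.97352 0.97716
#> sd   0.02023 0.01339

tt <- paired_ttest(rcv[, "brtok"], rcv[, "ok"])
#> paired t = -225.95, p = 2.3e-09, mean RMSE difference = -0.996

head(hybrid_importance(m), 5)
#>  variable     score rank
#>        V2 58.956669    1
#>        V1 21.581302    2
#>        V3 13.120813    3
#>        V5  3.305901    4
#>        V6  1.943874    5
```

Reading the output: the fitted residual variogram says about 64% of the
residual variance is spatially structured (partial sill 0.78 of sill 1.23)
with correlation up to distance 0.38 — so kriging the residuals has real
signal to use, and the hybrid halves OK's cross-validated RMSE (0.98 vs
1.97 on the response scale; the paired t-test over the five shared-fold
repeats rejects equality). The importance table attributes the trend to
the three covariates that truly drive it (`V1`–`V3` here).

A command-line wrapper with `simulate`, `fit`, `evaluate` and `importance`
subcommands lives at `inst/cli/mlkrige` (see `--help`; options can also be
supplied from a YAML file with explicit flags winning).

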