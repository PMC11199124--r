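test_that("a single stump attributes all influence to its split variable", {
  d <- random_dataset(60, 4, seed = 40)
  m <- fit_brt(d, brt_config(n_trees = 1, bag_fraction = 1,
                             learning_rate = 1, min_obs = 1, seed = 1))
  imp <- brt_importance(m)
  expect_equal(sum(imp$score), 100, tolerance = 1e-6)
  expect_equal(imp$score[1], 100, tolerance = 1e-12)
  expect_true(all(imp$score[-1] == 0))
})

test_that("BRT scores always normalize to 100 and rank planted signals first", {
  hits <- 0L
  for (seed in 1:20) {
    sim <- make_dataset(sim_spec(n = 250, p = 8, trend = "linear-sparse",
                                 active = 1:3, effects = c(2, 2, 2),
                                 residual_vm = variogram_model(0, 0, 1),
                                 noise_sd = 0.3, seed = seed))
    m <- fit_brt(sim$data, brt_config(n_trees = 100, seed = seed))
    imp <- brt_importance(m)
    expect_equal(sum(imp$score), 100, tolerance = 1e-6)
    if (imp$variable[1] %in% sim$truth$active_names) hits <- hits + 1L
  }
  expect_gte(hits, 19L)  # top-ranked variable is a planted one >= 95% of seeds
})

test_that("LASSO selection is exactly the nonzero set and recovers planted
           variables", {
  d <- random_dataset(60, 5, seed = 41)
  m_big <- fit_lasso(d, penalty = 2 * lasso_lambda_max(d))
  sel <- lasso_selection(m_big)
  expect_false(any(sel$selected))
  recovered <- 0L
  for (seed in 1:20) {
    sim <- make_dataset(sim_spec(n = 200, p = 10, trend = "linear-sparse",
                                 active = c(2, 5, 9), effects = c(1.5, 1.5, 1.5),
                                 residual_vm = variogram_model(0, 0, 1),
                                 noise_sd = 0.5, seed = 100 + seed))
    d_s <- preprocess_fit(sim$data)$data
    m <- fit_lasso(d_s, penalty = 0.1)
    tab <- lasso_selection(m)
    expect_setequal(tab$variable[tab$selected],
                    names(m$coefficients)[m$coefficients != 0])
    if (all(sim$truth$active_names %in% tab$variable[tab$selected]))
      recovered <- recovered + 1L
  }
  expect_gte(recovered, 18L)  # >= 90% of seeds
})

test_that("rankings are equivariant under covariate reordering", {
  d <- preprocess_fit(random_dataset(100, 5, seed = 42))$data
  d$response <- as.numeric(d$covariates %*% c(2, 0, 1, 0, 0.5)) + rnorm(100, sd = 0.3)
  m1 <- fit_lasso(d, penalty = 0.05, tol = 1e-10)
  perm <- c(4, 1, 5, 2, 3)
  d2 <- spatial_dataset(d$coords, d$response,
                        d$covariates[, perm], d$covariate_names[perm])
  m2 <- fit_lasso(d2, penalty = 0.05, tol = 1e-10)
  t1 <- lasso_selection(m1); t2 <- lasso_selection(m2)
  expect_equal(t1$variable, t2$variable)
  expect_equal(t1$score, t2$score, tolerance = 1e-6)
})

test_that("top-k frequency counts match a manual tally", {
  tab <- function(vars, scores)
    structure(data.frame(variable = vars[order(-scores, vars)],
                         score = sort(scores, decreasing = TRUE),
                         rank = seq_along(vars)),
              class = c("importance_table", "data.frame"))
  u <- c("a", "b", "c", "d")
  t1 <- tab(u, c(9, 5, 3, 1))
  t2 <- tab(u, c(1, 9, 5, 3))
  t3 <- tab(u, c(9, 5, 1, 3))
  fr <- topk_frequency(list(t1, t2, t3), k = 2)
  # manual tally of top-2 membership: a 2, b 3, c 1, d 0
  expect_equal(fr$frequency[match(c("a", "b", "c", "d"), fr$variable)],
               c(2L, 3L, 1L, 0L))
  expect_equal(fr$variable[1], "b")  # sorted by decreasing frequency
  # one dataset: exactly k ones; replicated tables: every count = d
  f1 <- topk_frequency(list(t1), k = 2)
  expect_equal(sum(f1$frequency), 2L)
  expect_true(all(f1$frequency %in% 0:1))
  f3 <- topk_frequency(list(t1, t1, t1), k = 2)
  expect_true(all(f3$frequency[f3$variable %in% c("a", "b")] == 3L))
  # inconsistent universes are rejected with the symmetric difference
  t4 <- tab(c("a", "b", "c", "z"), c(4, 3, 2, 1))
  expect_error(topk_frequency(list(t1, t4)), "z")
})

test_that("hybrid importance is exactly the trend model's importance", {
  d <- make_dataset(sim_spec(n = 150, p = 5, trend = "linear-sparse",
                             active = 1:2, effects = c(1, 1),
                             seed = 43))$data
  m <- fit_hybrid(d, "brt", brt_config(n_trees = 30, seed = 2), nMax = 15)
  expect_identical(hybrid_importance(m), brt_importance(m$trend))
})

test_that("ablation: empty drop is a no-op; dropping planted signals hurts;
           dropping noise stays within CV noise", {
  sim <- make_dataset(sim_spec(n = 200, p = 6, trend = "linear-sparse",
                               active = 1:2, effects = c(1.5, 1.5),
                               residual_vm = variogram_model(0.05, 0.3, 0.3),
                               noise_sd = 0.2, seed = 44))
  d <- sim$data
  algs <- list(lasok = list(nMax = 15, penalty = 0.02))
  base <- cross_validate(d, "lasok", algs$lasok,
                         folds = kfold_split(200, 5, seed = 3))
  none <- ablation_rerun(d, character(0), algs, k = 5, seed = 3)
  expect_equal(none$baseline_rmse, none$ablated_rmse)
  expect_equal(none$baseline_rmse, base$pooled_rmse)
  hurt <- ablation_rerun(d, sim$truth$active_names, algs, k = 5, seed = 3)
  expect_gt(hurt$delta, 0)  # removing real signal strictly worsens RMSE
  # removing pure-noise covariates moves RMSE by less than the fold spread
  noise_vars <- setdiff(d$covariate_names, sim$truth$active_names)[1:2]
  mild <- ablation_rerun(d, noise_vars, algs, k = 5, seed = 3)
  fold_sd <- sd(attr(mild, "folds")$baseline[, 1])
  expect_lt(abs(mild$delta), fold_sd)
  expect_error(ablation_rerun(d, "nope", algs), "unknown covariate")
})
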