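test_that("rmse matches hand arithmetic and validates input", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(1, 1)), 1)
  expect_equal(rmse(c(0, 0, 0, 0), c(1, 2, 3, 4)), sqrt(30 / 4))
  expect_error(rmse(1:3, 1:2), "length mismatch")
  expect_error(rmse(c(1, NA), c(1, 2)), "non-finite")
})

test_that("k-fold partitions are disjoint, exhaustive and balanced", {
  f <- kfold_split(10, 10, seed = 1)
  expect_length(f, 10)
  expect_true(all(lengths(f) == 1))
  f2 <- kfold_split(23, 10, seed = 2)
  expect_setequal(unlist(f2), 1:23)
  expect_equal(sum(lengths(f2) == 3L), 3L)
  expect_equal(sum(lengths(f2) == 2L), 7L)
  expect_identical(kfold_split(50, 5, seed = 7), kfold_split(50, 5, seed = 7))
  expect_false(identical(kfold_split(50, 5, seed = 7),
                         kfold_split(50, 5, seed = 8)))
  expect_error(kfold_split(5, 6), "k <= n")
})

test_that("cross_validate matches an explicit fold-loop oracle for BRT", {
  d <- make_dataset(sim_spec(n = 120, p = 4, trend = "linear-sparse",
                             active = 1:2, effects = c(1, 1),
                             seed = 30))$data
  cfg <- brt_config(n_trees = 40, seed = 5)
  folds <- kfold_split(120, 5, seed = 3)
  rep <- cross_validate(d, "brt", list(brt = cfg), folds = folds,
                        standardize = "none")
  # hand-rolled loop over the same folds
  obs <- pred <- numeric(0)
  fold_rmse <- numeric(5)
  for (f in seq_along(folds)) {
    tr <- subset_rows(d, -folds[[f]])
    te <- subset_rows(d, folds[[f]])
    p_f <- predict_trend(fit_brt(tr, cfg), te$covariates)
    fold_rmse[f] <- sqrt(mean((te$response - p_f)^2))
    obs <- c(obs, te$response); pred <- c(pred, p_f)
  }
  expect_equal(rep$fold_rmse, fold_rmse, tolerance = 1e-12)
  expect_equal(rep$pooled_rmse, sqrt(mean((obs - pred)^2)),
               tolerance = 1e-12)
})

test_that("pooled RMSE equals the monolithic recomputation over held-out points", {
  d <- make_dataset(sim_spec(n = 100, p = 3, trend = "linear-sparse",
                             active = 1:2, effects = c(1, -1),
                             seed = 31))$data
  rep <- cross_validate(d, "lasok", list(nMax = 15, penalty = 0.05),
                        k = 5, seed = 2, return_predictions = TRUE)
  expect_equal(rep$pooled_rmse,
               rmse(rep$predictions$observed, rep$predictions$predicted))
  expect_setequal(rep$predictions$index, 1:100)
})

test_that("a noiseless linear response is recovered almost perfectly by LASOK", {
  sim <- make_dataset(sim_spec(n = 150, p = 4, trend = "linear-sparse",
                               active = 1:3, effects = c(2, -1, 0.5),
                               residual_vm = variogram_model(0, 0, 1),
                               noise_sd = 1e-3, seed = 32))
  d <- sim$data
  rep <- cross_validate(d, "lasok", list(nMax = 20, penalty = 0.001),
                        k = 5, seed = 1, enforce_guard = FALSE)
  expect_lt(rep$pooled_rmse, 0.05 * sd(d$response))
})

test_that("cross-validation is deterministic under a fixed seed", {
  d <- make_dataset(sim_spec(n = 80, p = 3, trend = "linear-sparse",
                             active = 1:2, effects = c(1, 1), seed = 33))$data
  params <- list(nMax = 10, brt = brt_config(n_trees = 20, seed = 4))
  r1 <- cross_validate(d, "brtok", params, k = 5, seed = 9)
  r2 <- cross_validate(d, "brtok", params, k = 5, seed = 9)
  expect_identical(r1$fold_rmse, r2$fold_rmse)
  expect_identical(r1$pooled_rmse, r2$pooled_rmse)
})

test_that("grid search covers the grid, returns the minimizer, and breaks ties low", {
  d <- make_dataset(sim_spec(n = 90, p = 3, trend = "linear-sparse",
                             active = 1:2, effects = c(1, 1),
                             residual_vm = variogram_model(0.05, 0.4, 0.3),
                             noise_sd = 0.1, seed = 34))$data
  # single-point grid returns that point
  g1 <- grid_search(d, "ok", grid_spec(nMax = 25L, n_trees = 100L,
                                       lambda = 0.05), k = 5, seed = 1)
  expect_equal(g1$best$nMax, 25L)
  expect_equal(nrow(g1$table), 1L)
  # row count is the product of the searched grid sizes
  g2 <- grid_search(d, "lasok",
                    grid_spec(nMax = c(10L, 20L), n_trees = 100L,
                              lambda = c(0.02, 0.1, 0.5)),
                    k = 5, seed = 1, enforce_guard = FALSE)
  expect_equal(nrow(g2$table), 6L)
  expect_equal(g2$best_rmse, min(g2$table$rmse))
  # tie-breaking: duplicate rmse rows resolve to the smaller parameters
  tbl <- g2$table
  tied <- tbl[order(tbl$rmse, tbl$nMax, tbl$lambda), ][1, ]
  expect_equal(g2$best$nMax, tied$nMax)
  expect_equal(g2$best$lambda, tied$lambda)
})

test_that("repeated CV shares partitions within a repeat and reduces to
           cross_validate for a single repeat", {
  d <- make_dataset(sim_spec(n = 70, p = 3, trend = "linear-sparse",
                             active = 1:2, effects = c(1, 1), seed = 35))$data
  params <- list(nMax = 10)
  rcv <- repeated_cv(d, list(ok = params, ok.again = params),
                     repeats = 3, k = 5, seed = 11)
  # identical algorithm under two labels: identical columns <=> shared folds
  expect_identical(rcv[, "ok"], rcv[, "ok.again"])
  single <- cross_validate(d, "ok", params, k = 5, seed = 11)
  expect_identical(unname(rcv[1, "ok"]), single$pooled_rmse)
  expect_identical(attr(rcv, "fold_seeds"), 11:13)
})

test_that("paired t-test matches the closed form and handles degeneracy", {
  expect_equal(paired_ttest(c(1, 2, 3), c(1, 2, 3)),
               list(t = 0, p_value = 1, mean_diff = 0, df = 2L,
                    degenerate = FALSE))
  deg <- paired_ttest(c(2, 3, 4), c(1, 2, 3))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 0)
  # near-constant unit differences: overwhelming evidence
  set.seed(1)
  a <- rnorm(20, sd = 1e-6) + 1
  expect_lt(paired_ttest(a, rep(0, 20))$p_value, 1e-4)
  # textbook five-pair example, worked by hand:
  # d = (2, 4, 1, 3, 5): mean 3, sd sqrt(2.5), t = 3 / (sqrt(2.5)/sqrt(5))
  a <- c(12, 15, 9, 14, 16); b <- c(10, 11, 8, 11, 11)
  tt <- paired_ttest(a, b)
  expect_equal(tt$t, 3 / (sqrt(2.5) / sqrt(5)), tolerance = 1e-12)
  expect_equal(tt$df, 4L)
  expect_equal(tt$p_value, 2 * pt(-abs(tt$t), 4), tolerance = 1e-12)
  # and against the stock implementation
  st <- t.test(a, b, paired = TRUE)
  expect_equal(tt$t, unname(st$statistic), tolerance = 1e-12)
  expect_equal(tt$p_value, st$p.value, tolerance = 1e-12)
})
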