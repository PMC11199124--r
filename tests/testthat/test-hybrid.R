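# benchmark-style data shared across hybrid tests
hybrid_data <- function(seed = 1, n = 300) {
  make_dataset(sim_spec(n = n, p = 5, trend = "linear-sparse",
                        active = 1:2, effects = c(1, -1),
                        residual_vm = variogram_model(0.05, 0.5, 0.3),
                        noise_sd = 0.1, seed = seed))$data
}

test_that("the sample-size guard enforces n > 2p + 20", {
  sim <- make_dataset(small_n_spec(seed = 1))  # n = 90, p = 39 -> needs 98
  expect_error(fit_hybrid(sim$data, "lasso", list(penalty = 0.1)),
               "2p \\+ 20 = 98")
  expect_warning(
    m <- fit_hybrid(sim$data, "lasso", list(penalty = 0.1),
                    enforce_guard = FALSE),
    "ordinary kriging is recommended")
  expect_s3_class(m, "hybrid_model")
  # exactly at the boundary (n = 98 = 2p + 20) still refuses: needs strictly more
  d98 <- make_dataset(sim_spec(n = 98, p = 39, trend = "linear-sparse",
                               active = 1:2, effects = c(1, 1),
                               seed = 2))$data
  expect_error(fit_hybrid(d98, "lasso", list(penalty = 0.1)), "2p \\+ 20")
})

test_that("prediction is exactly trend plus residual kriging", {
  d <- hybrid_data(seed = 2)
  m <- fit_hybrid(d, "brt", brt_config(n_trees = 50, seed = 3), nMax = 20)
  set.seed(4)
  Xn <- matrix(rnorm(50 * 5), 50, 5)
  cn <- cbind(runif(50), runif(50))
  pred <- predict_hybrid(m, Xn, cn)
  trend_part <- predict_trend(m$trend, Xn)
  krig_part <- krige_grid(list(coords = m$train_coords,
                               values = m$train_residuals),
                          m$residual_variogram, cn, m$nMax)$value
  expect_identical(pred, trend_part + krig_part)
  # stored residuals are observed minus fitted, by definition
  expect_equal(m$train_residuals,
               d$response - predict_trend(m$trend, d$covariates))
})

test_that("a perfect linear trend leaves nothing for kriging", {
  set.seed(5)
  n <- 120
  X <- matrix(rnorm(n * 3), n, 3)
  d <- spatial_dataset(cbind(runif(n), runif(n)),
                       1 + as.numeric(X %*% c(2, -1, 0.5)), X)
  m <- fit_hybrid(d, "lasso", list(penalty = 0, tol = 1e-12), nMax = 15)
  expect_lt(max(abs(m$train_residuals)), 1e-6)
  pred <- predict_hybrid(m, d$covariates, d$coords)
  expect_equal(pred, d$response, tolerance = 1e-6)
})

test_that("zero-nugget residual structure interpolates training data exactly", {
  d <- hybrid_data(seed = 6, n = 100)
  m <- fit_hybrid(d, "brt", brt_config(n_trees = 30, seed = 1), nMax = 25)
  m$residual_variogram <- variogram_model(0, 1, 0.4)  # force c0 = 0
  pred <- predict_hybrid(m, d$covariates, d$coords)
  expect_equal(pred, d$response, tolerance = 1e-8)
})

test_that("pure-nugget residuals reduce kriging to the neighborhood mean", {
  d <- hybrid_data(seed = 7, n = 100)
  m <- fit_hybrid(d, "lasso", list(penalty = 0.01), nMax = 10)
  m$residual_variogram <- variogram_model(0.5, 0, 1)  # white residuals
  x0 <- c(0.42, 0.58)
  pred <- predict_hybrid(m, matrix(0, 1, 5), rbind(x0))
  d0 <- sqrt(colSums((t(m$train_coords) - x0)^2))
  nb <- order(d0)[1:10]
  expect_equal(pred,
               predict_trend(m$trend, matrix(0, 1, 5)) +
                 mean(m$train_residuals[nb]),
               tolerance = 1e-10)
})

test_that("kriging the residuals improves out-of-sample accuracy when the
           residual field is spatially structured", {
  wins <- 0L
  for (seed in 1:50) {
    sim <- make_dataset(sim_spec(n = 250, p = 4, trend = "linear-sparse",
                                 active = 1:2, effects = c(1, -1),
                                 residual_vm = variogram_model(0.05, 0.6, 0.4),
                                 noise_sd = 0.1, seed = seed))
    train <- subset_rows(sim$data, 1:200)
    test <- subset_rows(sim$data, 201:250)
    m <- fit_hybrid(train, "lasso", list(penalty = 0.01), nMax = 25)
    hyb <- predict_hybrid(m, test$covariates, test$coords)
    trd <- predict_trend(m$trend, test$covariates)
    if (rmse(test$response, hyb) < rmse(test$response, trd))
      wins <- wins + 1L
  }
  expect_gte(wins, 45L)  # >= 90% of seeds
})

test_that("hybrid serialization round-trips predictions", {
  d <- hybrid_data(seed = 8, n = 120)
  m <- fit_hybrid(d, "brt", brt_config(n_trees = 20, seed = 2), nMax = 15)
  dir <- withr::local_tempdir()
  write_hybrid_dir(m, dir)
  m2 <- read_hybrid_dir(dir)
  set.seed(9)
  Xn <- matrix(rnorm(10 * 5), 10, 5)
  cn <- cbind(runif(10), runif(10))
  expect_equal(predict_hybrid(m2, Xn, cn), predict_hybrid(m, Xn, cn),
               tolerance = 1e-10)
})
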