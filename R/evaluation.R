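#' Root mean squared error
#'
#' `sqrt(mean((observed - predicted)^2))` — the accuracy metric used for all
#' model comparison.
#'
#' @param observed,predicted Equal-length finite numeric vectors.
#' @return Nonnegative scalar.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("length mismatch: ", length(observed), " vs ", length(predicted))
  if (length(observed) == 0L) stop("empty input")
  if (!all(is.finite(observed)) || !all(is.finite(predicted)))
    stop("non-finite values in input")
  sqrt(mean((observed - predicted)^2))
}

#' Random k-fold partition
#'
#' Randomly divides `1..n` into `k` disjoint, exhaustive folds whose sizes
#' differ by at most one; reproducible under `seed`.
#'
#' @param n Number of observations.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Integer seed.
#' @return List of `k` integer index vectors (the test sets).
#' @export
kfold_split <- function(n, k, seed = 1L) {
  if (k < 2L || k > n) stop("need 2 <= k <= n (n = ", n, ", k = ", k, ")")
  perm <- with_seed(seed, sample.int(n))
  fold_of <- rep(seq_len(k), length.out = n)  # sizes differ by <= 1
  split(perm, fold_of)
}

#' k-fold cross-validation of one spatial prediction algorithm
#'
#' For each fold the model is fitted on the remaining `k - 1` folds
#' (including, for the hybrids, refitting the residual variogram on that
#' training fold; for plain OK, fitting the variogram of the response
#' itself on the training fold) and the held-out points are predicted.
#' Returns per-fold RMSEs and the pooled RMSE over the concatenation of all
#' held-out predictions.
#'
#' @param data A [spatial_dataset()] (response already on the modelling
#'   scale, e.g. log-transformed).
#' @param algorithm One of `"ok"`, `"brt"`, `"brtok"`, `"lasok"`.
#' @param params Named list of algorithm parameters: `nMax` (ok, brtok,
#'   lasok), `brt` (a [brt_config()]; brt, brtok), `penalty` (lasok).
#' @param k Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @param folds Optional precomputed partition (as from [kfold_split()]);
#'   overrides `k`/`seed`. Required to share folds across algorithms for
#'   paired comparisons.
#' @param standardize `"global"` (standardize covariates once on the full
#'   dataset before splitting — mirrors common practice with
#'   pre-standardized ecological layers), `"per_fold"` (leakage-free:
#'   statistics fitted on each training fold), or `"none"`.
#' @param n_bins,cutoff Variogram binning passed through.
#' @param enforce_guard Enforce the `n > 2p + 20` training-size rule for
#'   hybrid fits (see [fit_hybrid()]).
#' @param return_predictions Keep the held-out predictions in the report?
#' @return An object of class `cv_report`: algorithm, params, `fold_rmse`,
#'   `pooled_rmse`, `seed`, and optionally `predictions`.
#' @export
cross_validate <- function(data, algorithm = c("ok", "brt", "brtok", "lasok"),
                           params = list(), k = 10L, seed = 1L,
                           folds = NULL,
                           standardize = c("global", "per_fold", "none"),
                           n_bins = 15L, cutoff = NULL,
                           enforce_guard = TRUE,
                           return_predictions = FALSE) {
  algorithm <- match.arg(algorithm)
  standardize <- match.arg(standardize)
  n <- n_points(data)
  if (is.null(folds)) folds <- kfold_split(n, k, seed)
  k <- length(folds)
  if (standardize == "global" && n_covariates(data) > 0L)
    data <- preprocess_fit(data)$data
  obs_all <- pred_all <- numeric(0)
  fold_rmse <- numeric(k)
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    res <- tryCatch(
      .cv_fold(data, algorithm, params, test_idx, standardize,
               n_bins, cutoff, enforce_guard),
      error = function(e)
        stop("cross-validation failed at fold ", f, " (", algorithm,
             "): ", conditionMessage(e)))
    fold_rmse[f] <- rmse(res$obs, res$pred)
    obs_all <- c(obs_all, res$obs)
    pred_all <- c(pred_all, res$pred)
  }
  out <- list(algorithm = algorithm, params = params,
              fold_rmse = fold_rmse,
              pooled_rmse = rmse(obs_all, pred_all),
              k = k, seed = seed)
  if (return_predictions) {
    out$predictions <- data.frame(index = unlist(folds, use.names = FALSE),
                                  fold = rep(seq_len(k), lengths(folds)),
                                  observed = obs_all, predicted = pred_all)
  }
  structure(out, class = "cv_report")
}

.cv_fold <- function(data, algorithm, params, test_idx, standardize,
                     n_bins, cutoff, enforce_guard) {
  train <- subset_rows(data, -test_idx)
  test <- subset_rows(data, test_idx)
  if (standardize == "per_fold" && n_covariates(data) > 0L) {
    pp <- preprocess_fit(train)
    train <- pp$data
    test$covariates <- pp_transform_covariates(pp$pre, test$covariates)
  }
  nMax <- params$nMax %||% 30L
  brt_cfg <- params$brt %||% brt_config()
  pred <- switch(algorithm,
    ok = {
      ev <- empirical_variogram(train, n_bins = n_bins, cutoff = cutoff)
      vm <- fit_spherical(ev)
      krige_grid(train, vm, test$coords, nMax)$value
    },
    brt = predict_trend(fit_brt(train, brt_cfg), test$covariates),
    brtok = predict_hybrid(
      fit_hybrid(train, "brt", brt_cfg, nMax = nMax, n_bins = n_bins,
                 cutoff = cutoff, enforce_guard = enforce_guard),
      test$covariates, test$coords),
    lasok = predict_hybrid(
      fit_hybrid(train, "lasso",
                 list(penalty = params$penalty %||% 0.01),
                 nMax = nMax, n_bins = n_bins, cutoff = cutoff,
                 enforce_guard = enforce_guard),
      test$covariates, test$coords))
  list(obs = test$response, pred = pred)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$algorithm, ", ", x$k, "-fold: pooled RMSE ",
      signif(x$pooled_rmse, 5), " (fold range ",
      signif(min(x$fold_rmse), 4), "-", signif(max(x$fold_rmse), 4), ")\n",
      sep = "")
  invisible(x)
}

#' Parameter grids for cross-validated tuning
#'
#' Default search windows: `nMax` 10–150 (step 5), `n_trees` 100–800
#' (step 50), `lambda` 0.01–1 (step 0.005).
#'
#' @param nMax,n_trees,lambda Ascending numeric grids.
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(nMax = seq(10L, 150L, by = 5L),
                      n_trees = seq(100L, 800L, by = 50L),
                      lambda = seq(0.01, 1, by = 0.005)) {
  chk <- function(g, nm) {
    if (length(g) == 0L || is.unsorted(g, strictly = TRUE))
      stop("grid `", nm, "` must be nonempty and strictly ascending")
    g
  }
  structure(list(nMax = chk(nMax, "nMax"), n_trees = chk(n_trees, "n_trees"),
                 lambda = chk(lambda, "lambda")),
            class = "grid_spec")
}

#' Cross-validated grid search for the tuning parameters
#'
#' Evaluates every parameter combination relevant to the algorithm (OK:
#' `nMax`; BRT: `n_trees`; BRTOK: `nMax` x `n_trees`; LASOK: `nMax` x
#' `lambda`) with [cross_validate()] on a shared fold partition and returns
#' the pooled-RMSE minimizer. Ties are broken by smaller `nMax`, then
#' smaller `n_trees` / `lambda`.
#'
#' @inheritParams cross_validate
#' @param grid A [grid_spec()].
#' @param brt_base A [brt_config()] supplying the non-tuned BRT settings.
#' @param ... Passed to [cross_validate()].
#' @return List with `best` (named parameter list), `best_rmse`, and
#'   `table` (a data frame of all evaluated points).
#' @export
grid_search <- function(data, algorithm = c("ok", "brt", "brtok", "lasok"),
                        grid = grid_spec(), k = 10L, seed = 1L,
                        brt_base = brt_config(), ...) {
  algorithm <- match.arg(algorithm)
  folds <- kfold_split(n_points(data), k, seed)
  combos <- switch(algorithm,
    ok = data.frame(nMax = grid$nMax),
    brt = data.frame(n_trees = grid$n_trees),
    brtok = expand.grid(nMax = grid$nMax, n_trees = grid$n_trees,
                        KEEP.OUT.ATTRS = FALSE),
    lasok = expand.grid(nMax = grid$nMax, lambda = grid$lambda,
                        KEEP.OUT.ATTRS = FALSE))
  combos$rmse <- NA_real_
  for (i in seq_len(nrow(combos))) {
    params <- as.list(combos[i, setdiff(names(combos), "rmse"), drop = FALSE])
    if (!is.null(params$n_trees)) {
      brt_base$n_trees <- as.integer(params$n_trees)
      params$brt <- brt_base
    }
    if (!is.null(params$lambda)) params$penalty <- params$lambda
    rep <- tryCatch(
      cross_validate(data, algorithm, params, folds = folds, ...),
      error = function(e)
        stop("grid search failed at ",
             paste(names(combos)[-ncol(combos)], "=",
                   unlist(combos[i, -ncol(combos)]), collapse = ", "),
             ": ", conditionMessage(e)))
    combos$rmse[i] <- rep$pooled_rmse
  }
  ord_cols <- intersect(c("nMax", "n_trees", "lambda"), names(combos))
  ord <- do.call(order, c(list(combos$rmse), combos[ord_cols]))
  best_row <- combos[ord[1L], ]
  best <- as.list(best_row[setdiff(names(best_row), "rmse")])
  list(best = best, best_rmse = best_row$rmse, table = combos)
}

#' Repeated k-fold cross-validation with shared partitions
#'
#' Repeats the k-fold protocol `repeats` times; repeat `r` uses the fold
#' seed `seed + r - 1`, and within a repeat every algorithm is evaluated on
#' the identical partition — the pairing required for the paired t-test.
#' With `repeats = 1` this reduces to one [cross_validate()] call per
#' algorithm.
#'
#' @inheritParams cross_validate
#' @param algorithms Named list: each element is the `params` list for the
#'   algorithm given by its name (names in ok/brt/brtok/lasok; a name may
#'   carry a suffix after a dot to evaluate one algorithm twice).
#' @param repeats Number of repeats (default 100).
#' @param ... Passed to [cross_validate()].
#' @return A `repeats x length(algorithms)` matrix of pooled RMSEs (class
#'   `repeated_cv`), with the per-repeat fold seeds as an attribute.
#' @export
repeated_cv <- function(data, algorithms, repeats = 100L, k = 10L,
                        seed = 1L, ...) {
  stopifnot(length(algorithms) >= 1L, !is.null(names(algorithms)))
  algs <- sub("\\..*$", "", names(algorithms))
  if (!all(algs %in% c("ok", "brt", "brtok", "lasok")))
    stop("unknown algorithm in: ", paste(names(algorithms), collapse = ", "))
  out <- matrix(NA_real_, nrow = repeats, ncol = length(algorithms),
                dimnames = list(NULL, names(algorithms)))
  fold_seeds <- as.integer(seed) + seq_len(repeats) - 1L
  n <- n_points(data)
  for (r in seq_len(repeats)) {
    folds <- kfold_split(n, k, fold_seeds[r])
    for (j in seq_along(algorithms)) {
      rep_j <- cross_validate(data, algs[j], algorithms[[j]],
                              folds = folds, seed = fold_seeds[r], ...)
      out[r, j] <- rep_j$pooled_rmse
    }
  }
  structure(out, fold_seeds = fold_seeds, k = k, class = "repeated_cv")
}

#' @export
print.repeated_cv <- function(x, ...) {
  cat("<repeated_cv> ", nrow(x), " repeats of ", attr(x, "k"),
      "-fold CV\n", sep = "")
  print(round(rbind(mean = colMeans(x), sd = apply(x, 2L, stats::sd)), 5))
  invisible(x)
}

#' Paired-samples t-test on per-repeat RMSEs
#'
#' Classical paired t on the differences `a - b` with `R - 1` degrees of
#' freedom, two-sided. The pairs must come from shared fold partitions (as
#' produced by [repeated_cv()]). Degenerate cases: all differences exactly
#' zero gives `t = 0, p = 1`; zero-variance differences with nonzero mean
#' give `p = 0` and set the `degenerate` flag.
#'
#' @param rmse_a,rmse_b Equal-length (R >= 2) numeric vectors.
#' @return List: `t`, `p_value`, `mean_diff`, `df`, `degenerate`.
#' @export
paired_ttest <- function(rmse_a, rmse_b) {
  R <- length(rmse_a)
  if (length(rmse_b) != R) stop("length mismatch")
  if (R < 2L) stop("need at least 2 pairs")
  d <- rmse_a - rmse_b
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (md == 0)
      return(list(t = 0, p_value = 1, mean_diff = 0, df = R - 1L,
                  degenerate = FALSE))
    return(list(t = sign(md) * Inf, p_value = 0, mean_diff = md,
                df = R - 1L, degenerate = TRUE))
  }
  t <- md / (sdd / sqrt(R))
  list(t = t, p_value = 2 * stats::pt(-abs(t), df = R - 1L),
       mean_diff = md, df = R - 1L, degenerate = FALSE)
}

#' Write a tidy CSV of repeated-CV results
#'
#' One row per (repeat, algorithm) with the pooled RMSE — the long format
#' behind box-plot style model comparisons.
#'
#' @param rcv A [repeated_cv()] matrix.
#' @param path Output CSV path.
#' @return `path` invisibly.
#' @export
write_cv_csv <- function(rcv, path) {
  df <- data.frame(repeat_index = rep(seq_len(nrow(rcv)), ncol(rcv)),
                   algorithm = rep(colnames(rcv), each = nrow(rcv)),
                   rmse = as.vector(rcv))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
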