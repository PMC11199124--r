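#' Fit a hybrid trend + residual-kriging model (BRTOK / LASOK)
#'
#' The three-step construction behind the hybrids: (1) fit a machine-learning
#' trend (boosted regression trees or LASSO) to the covariates; (2) compute
#' its residuals `e(x_i) = observed - fitted` at every training location and
#' fit a spherical variogram to their empirical semivariogram; (3) predict at
#' a new location as trend plus ordinary kriging of the residual field:
#' \deqn{\hat y(x_0) = \hat m(x_0) + \hat e(x_0),\qquad
#'       \hat e(x_0) = \sum_i \lambda_i\, e(x_i)}
#' with the kriging weights determined by the residual spatial-dependence
#' structure over the `nMax` nearest training points.
#'
#' Training data smaller than `2p + 20` rows cannot reliably support the
#' trend fit (see [min_train_size()]); such data raise an error unless
#' `enforce_guard = FALSE`, which downgrades it to a warning — with very
#' small samples plain ordinary kriging is usually the better tool.
#'
#' @param data A [spatial_dataset()] (covariates already standardized and
#'   response already transformed as desired; see [preprocess_fit()]).
#' @param trend_kind `"brt"` or `"lasso"`.
#' @param trend_cfg For `"brt"` a [brt_config()]; for `"lasso"` a list with
#'   `penalty` (and optionally `tol`, `max_iter`).
#' @param nMax Kriging search-window size (number of nearest neighbors).
#' @param n_bins,cutoff Variogram binning for the residual field, passed to
#'   [empirical_variogram()].
#' @param enforce_guard If `TRUE` (default) violating `n > 2p + 20` is an
#'   error; if `FALSE` it is a warning.
#' @return An object of class `hybrid_model`: the fitted trend, the residual
#'   [variogram_model()], the training residual field, and `nMax`.
#' @export
fit_hybrid <- function(data, trend_kind = c("brt", "lasso"),
                       trend_cfg = NULL, nMax = 30L,
                       n_bins = 15L, cutoff = NULL,
                       enforce_guard = TRUE) {
  trend_kind <- match.arg(trend_kind)
  n <- n_points(data)
  p <- n_covariates(data)
  guard <- min_train_size(p)
  if (n <= guard) {
    msg <- paste0("training size n = ", n, " does not exceed 2p + 20 = ",
                  guard, " (p = ", p, "); hybrid trend fitting is ",
                  "unreliable here and plain ordinary kriging is ",
                  "recommended")
    if (enforce_guard)
      stop(msg, "; set enforce_guard = FALSE to proceed anyway")
    warning(msg)
  }
  trend <- switch(trend_kind,
    brt = fit_brt(data, if (is.null(trend_cfg)) brt_config() else trend_cfg),
    lasso = {
      cfg <- if (is.null(trend_cfg)) list(penalty = 0.01) else trend_cfg
      do.call(fit_lasso, c(list(data = data), cfg))
    })
  fitted <- predict_trend(trend, data$covariates)
  resid <- data$response - fitted
  vm <- tryCatch({
    ev <- empirical_variogram(list(coords = data$coords, values = resid),
                              n_bins = n_bins, cutoff = cutoff)
    fit_spherical(ev)
  }, error = function(e)
    stop("residual variogram fit failed (", conditionMessage(e),
         "); consider using the trend model alone"))
  structure(list(trend = trend,
                 residual_variogram = vm,
                 train_coords = data$coords,
                 train_residuals = resid,
                 nMax = as.integer(nMax)),
            class = "hybrid_model")
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat("<hybrid_model> trend: ", x$trend$kind, " + residual ordinary kriging",
      " (nMax ", x$nMax, ")\n", sep = "")
  print(x$residual_variogram)
  invisible(x)
}

#' Predict from a hybrid model
#'
#' Exactly the sum of [predict_trend()] on the covariates and [krige_grid()]
#' on the stored residual field: `yhat(x0) = mhat(x0) + ehat(x0)`.
#'
#' @param model A fitted [fit_hybrid()] model.
#' @param X_new `m x p` covariate matrix (same preprocessing scale as
#'   training).
#' @param coords_new `m x 2` matrix of prediction locations.
#' @param se Also return residual-kriging variances?
#' @return Length-`m` numeric vector of predictions, or (with `se = TRUE`) a
#'   data frame with `value` and `residual_variance`.
#' @export
predict_hybrid <- function(model, X_new, coords_new, se = FALSE) {
  X_new <- as.matrix(X_new)
  coords_new <- as.matrix(coords_new)
  if (nrow(X_new) != nrow(coords_new))
    stop("X_new and coords_new must have the same number of rows")
  mhat <- predict_trend(model$trend, X_new)
  kr <- krige_grid(list(coords = model$train_coords,
                        values = model$train_residuals),
                   model$residual_variogram, coords_new, model$nMax)
  val <- mhat + kr$value
  if (se) data.frame(value = val, residual_variance = kr$variance) else val
}

#' Serialize a hybrid model to a directory
#'
#' Writes the trend model as JSON, the residual variogram as JSON, and the
#' residual field as CSV; [read_hybrid_dir()] restores the bundle.
#'
#' @param model A `hybrid_model`.
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly / a `hybrid_model`.
#' @export
write_hybrid_dir <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (model$trend$kind == "brt")
    write_brt_json(model$trend, file.path(dir, "trend_brt.json"))
  else
    write_lasso_json(model$trend, file.path(dir, "trend_lasso.json"))
  write_variogram_json(model$residual_variogram,
                       file.path(dir, "residual_variogram.json"))
  utils::write.csv(data.frame(x = model$train_coords[, 1L],
                              y = model$train_coords[, 2L],
                              residual = model$train_residuals),
                   file.path(dir, "residuals.csv"), row.names = FALSE)
  jsonlite::write_json(list(nMax = model$nMax),
                       file.path(dir, "hybrid.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_hybrid_dir
#' @export
read_hybrid_dir <- function(dir) {
  trend <- if (file.exists(file.path(dir, "trend_brt.json")))
    read_brt_json(file.path(dir, "trend_brt.json"))
  else
    read_lasso_json(file.path(dir, "trend_lasso.json"))
  res <- utils::read.csv(file.path(dir, "residuals.csv"))
  meta <- jsonlite::read_json(file.path(dir, "hybrid.json"),
                              simplifyVector = TRUE)
  structure(list(trend = trend,
                 residual_variogram =
                   read_variogram_json(file.path(dir, "residual_variogram.json")),
                 train_coords = cbind(res$x, res$y),
                 train_residuals = res$residual,
                 nMax = as.integer(meta$nMax)),
            class = "hybrid_model")
}
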