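#' Configuration for boosted regression trees
#'
#' @param n_trees Number of boosting iterations (the tuning parameter
#'   `nTrees`; typical search range 100–800).
#' @param learning_rate Shrinkage applied to every tree, in (0, 1];
#'   default 0.1.
#' @param max_depth Depth of each tree; default 1 (additive stumps).
#' @param bag_fraction Fraction of rows subsampled (without replacement)
#'   for each tree, in (0, 1]; default 0.5.
#' @param min_obs Minimum observations per terminal node; default 10.
#' @param seed Integer seed governing all bagging draws; recorded in the
#'   fitted model so a fit is exactly reproducible.
#' @return A list of class `brt_config`.
#' @export
brt_config <- function(n_trees = 100L, learning_rate = 0.1, max_depth = 1L,
                       bag_fraction = 0.5, min_obs = 10L, seed = 1L) {
  stopifnot(n_trees >= 1L, learning_rate > 0, learning_rate <= 1,
            max_depth >= 1L, bag_fraction > 0, bag_fraction <= 1,
            min_obs >= 1L)
  structure(list(n_trees = as.integer(n_trees),
                 learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 bag_fraction = bag_fraction,
                 min_obs = as.integer(min_obs),
                 seed = as.integer(seed)),
            class = "brt_config")
}

# run expr under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fit a boosted-regression-tree trend model
#'
#' Gradient boosting for squared-error loss: the fit starts from the
#' response mean, then iteratively grows a depth-limited regression tree on
#' the current residuals (over a `bag_fraction` subsample) and adds it to
#' the ensemble scaled by the learning rate. Split search is exhaustive over
#' all features and split points (maximum SSE reduction). Training deviance
#' (mean squared training error) is recorded per iteration.
#'
#' @param data A [spatial_dataset()] with `p >= 1` covariates.
#' @param cfg A [brt_config()].
#' @return An object of class `brt_model` (also `trend_model`) holding the
#'   tree ensemble, initial value, per-iteration training deviance, the
#'   configuration, and feature names.
#' @examples
#' d <- spatial_dataset(cbind(runif(60), runif(60)), rnorm(60),
#'                      matrix(rnorm(120), 60, 2))
#' m <- fit_brt(d, brt_config(n_trees = 25, seed = 7))
#' head(predict_trend(m, d$covariates))
#' @export
fit_brt <- function(data, cfg = brt_config()) {
  X <- data$covariates
  y <- data$response
  n <- nrow(X)
  if (ncol(X) == 0L) stop("BRT requires at least one covariate (p >= 1)")
  if (n < 2L) stop("BRT requires at least 2 observations")
  bag_size <- max(1L, floor(cfg$bag_fraction * n))
  bags <- with_seed(cfg$seed, {
    matrix(vapply(seq_len(cfg$n_trees),
                  function(i) sample.int(n, bag_size),
                  integer(bag_size)),
           nrow = bag_size)
  })
  fit <- boost_fit_cpp(X, y, bags, cfg$learning_rate, cfg$max_depth,
                       cfg$min_obs)
  structure(list(kind = "brt",
                 init = fit$init,
                 trees = fit$trees,
                 train_deviance = fit$train_deviance,
                 config = cfg,
                 feature_names = data$covariate_names),
            class = c("brt_model", "trend_model"))
}

#' @export
print.brt_model <- function(x, ...) {
  cat("<brt_model> ", length(x$trees), " trees, depth ",
      x$config$max_depth, ", learning rate ", x$config$learning_rate,
      ", seed ", x$config$seed, "\n", sep = "")
  cat("  final training deviance: ",
      signif(utils::tail(x$train_deviance, 1L), 5), "\n", sep = "")
  invisible(x)
}

#' Predict from a fitted trend model
#'
#' Deterministic evaluation of a fitted [fit_brt()] or [fit_lasso()] model
#' on new covariate rows.
#'
#' @param model A fitted `trend_model`.
#' @param X `m x p` numeric covariate matrix with `p` matching the training
#'   data.
#' @return Length-`m` numeric vector of fitted trend values.
#' @export
predict_trend <- function(model, X) UseMethod("predict_trend")

check_p <- function(model, X) {
  X <- as.matrix(X)
  p <- length(model$feature_names)
  if (ncol(X) != p)
    stop("covariate matrix has ", ncol(X), " columns but the model was ",
         "trained with ", p)
  storage.mode(X) <- "double"
  X
}

#' @export
predict_trend.brt_model <- function(model, X) {
  X <- check_p(model, X)
  as.numeric(boost_predict_cpp(model$trees, model$init,
                               model$config$learning_rate, X))
}

#' @export
predict.brt_model <- function(object, newdata, ...) predict_trend(object, newdata)

#' Serialize / restore a BRT trend model as JSON
#'
#' Trees are stored as nested split records (node arrays), versioned.
#'
#' @param model A `brt_model`.
#' @param path File path.
#' @return `path` invisibly / a `brt_model`.
#' @export
write_brt_json <- function(model, path) {
  out <- list(format = "mlkrige-brt-1", kind = "brt", init = model$init,
              learning_rate = model$config$learning_rate,
              config = unclass(model$config),
              feature_names = model$feature_names,
              train_deviance = model$train_deviance,
              trees = lapply(model$trees, function(t) lapply(t, as.vector)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_brt_json
#' @export
read_brt_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "mlkrige-brt-1"))
    stop("unrecognized BRT serialization format: ", x$format)
  trees <- lapply(seq_len(nrow_or_len(x$trees)), function(i) tree_record(x$trees, i))
  cfg <- do.call(brt_config, x$config[c("n_trees", "learning_rate",
                                        "max_depth", "bag_fraction",
                                        "min_obs", "seed")])
  structure(list(kind = "brt", init = x$init, trees = trees,
                 train_deviance = x$train_deviance, config = cfg,
                 feature_names = x$feature_names),
            class = c("brt_model", "trend_model"))
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

tree_record <- function(trees, i) {
  t <- if (is.data.frame(trees)) lapply(trees, `[[`, i) else trees[[i]]
  list(var = as.integer(t$var), split = as.numeric(t$split),
       left = as.integer(t$left), right = as.integer(t$right),
       value = as.numeric(t$value), improve = as.numeric(t$improve))
}
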