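#' Fit a LASSO trend model by cyclic coordinate descent
#'
#' Solves the l1-penalized least-squares problem
#' \deqn{\hat\beta_\lambda = \arg\min_{\beta_0,\beta}\;
#'   \frac{1}{N}\sum_{i=1}^N (y_i - \beta_0 - x_i^T\beta)^2
#'   + \lambda \lVert\beta\rVert_1}
#' by cyclic coordinate descent with soft-thresholding; the intercept is
#' unpenalized. Note the objective carries a `1/N` factor on the residual
#' sum of squares and no `1/2`: on this scale the coordinate update is
#' `beta_j = S(z_j, lambda) / (2 v_j)` with `z_j = (2/N) x_j' r_j`,
#' `v_j = (1/N) x_j' x_j`, and the smallest penalty shrinking every slope
#' to zero is `lambda_max = max_j |(2/N) x_j'(y - ybar)|`. (Solvers that
#' use `(1/2N) RSS`, such as glmnet, match this fit at `lambda / 2`.)
#'
#' Covariates are expected to be standardized (see [preprocess_fit()]); the
#' penalty then acts uniformly across features and coefficient magnitudes
#' are comparable for importance ranking.
#'
#' @param data A [spatial_dataset()] with `p >= 1` covariates.
#' @param penalty Penalty level `lambda >= 0` on the objective scale above
#'   (typical search range 0.01–1).
#' @param tol Convergence tolerance on the maximum absolute coefficient
#'   change per sweep; default 1e-7.
#' @param max_iter Maximum number of full coordinate sweeps; default 1e5.
#' @return An object of class `lasso_model` (also `trend_model`): intercept,
#'   coefficient vector, `selected` (indices of nonzero coefficients),
#'   penalty, iteration count, and feature names.
#' @examples
#' d <- spatial_dataset(cbind(runif(50), runif(50)), rnorm(50),
#'                      scale(matrix(rnorm(150), 50, 3)))
#' fit_lasso(d, penalty = 0.05)
#' @export
fit_lasso <- function(data, penalty, tol = 1e-7, max_iter = 1e5L) {
  X <- data$covariates
  y <- data$response
  n <- nrow(X)
  p <- ncol(X)
  if (p == 0L) stop("LASSO requires at least one covariate (p >= 1)")
  if (n < 2L) stop("LASSO requires at least 2 observations")
  if (penalty < 0) stop("penalty must be >= 0")
  v <- colSums(X^2) / n                  # (1/N) x_j'x_j
  if (any(v == 0)) stop("zero-variance covariate at column ",
                        which(v == 0)[1L])
  beta <- numeric(p)
  b0 <- mean(y)
  r <- y - b0                            # full residual y - b0 - X beta
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  it <- 0L
  repeat {
    it <- it + 1L
    delta <- 0
    for (j in seq_len(p)) {
      bj <- beta[j]
      z <- 2 * sum(X[, j] * r) / n + 2 * v[j] * bj   # (2/N) x_j' r_j
      bnew <- soft(z, penalty) / (2 * v[j])
      if (bnew != bj) {
        r <- r - X[, j] * (bnew - bj)
        beta[j] <- bnew
        delta <- max(delta, abs(bnew - bj))
      }
    }
    b0new <- b0 + mean(r)
    delta <- max(delta, abs(b0new - b0))
    r <- r - (b0new - b0)
    b0 <- b0new
    if (delta < tol) break
    if (it >= max_iter)
      stop("LASSO coordinate descent did not converge in ", max_iter,
           " sweeps (last max coefficient change ", signif(delta, 4), ")")
  }
  names(beta) <- data$covariate_names
  structure(list(kind = "lasso", intercept = b0, coefficients = beta,
                 penalty = penalty, selected = which(beta != 0),
                 n_iter = it, feature_names = data$covariate_names),
            class = c("lasso_model", "trend_model"))
}

#' @export
print.lasso_model <- function(x, ...) {
  cat("<lasso_model> lambda ", x$penalty, ": ", length(x$selected), " of ",
      length(x$coefficients), " covariates selected (",
      x$n_iter, " sweeps)\n", sep = "")
  invisible(x)
}

#' @export
predict_trend.lasso_model <- function(model, X) {
  X <- check_p(model, X)
  as.numeric(model$intercept + X %*% model$coefficients)
}

#' @export
predict.lasso_model <- function(object, newdata, ...) predict_trend(object, newdata)

#' Smallest penalty that zeroes every LASSO slope
#'
#' On the implemented objective scale, `lambda_max =
#' max_j |(2/N) x_j'(y - ybar)|`; at or above this penalty the fit is the
#' intercept-only model.
#'
#' @param data A [spatial_dataset()].
#' @return `lambda_max`.
#' @export
lasso_lambda_max <- function(data) {
  X <- data$covariates
  y <- data$response
  n <- nrow(X)
  r <- y - mean(y)
  # same arithmetic as the coordinate update, so that at penalty ==
  # lambda_max the soft threshold lands exactly on zero
  max(vapply(seq_len(ncol(X)), function(j) abs(2 * sum(X[, j] * r) / n), 0))
}

#' Serialize / restore a LASSO trend model as JSON
#' @param model A `lasso_model`.
#' @param path File path.
#' @return `path` invisibly / a `lasso_model`.
#' @export
write_lasso_json <- function(model, path) {
  out <- list(format = "mlkrige-lasso-1", kind = "lasso",
              intercept = model$intercept,
              coefficients = as.numeric(model$coefficients),
              penalty = model$penalty, feature_names = model$feature_names)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lasso_json
#' @export
read_lasso_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "mlkrige-lasso-1"))
    stop("unrecognized LASSO serialization format: ", x$format)
  beta <- as.numeric(x$coefficients)
  names(beta) <- x$feature_names
  structure(list(kind = "lasso", intercept = x$intercept,
                 coefficients = beta, penalty = x$penalty,
                 selected = which(beta != 0), n_iter = NA_integer_,
                 feature_names = x$feature_names),
            class = c("lasso_model", "trend_model"))
}
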