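#' Fit preprocessing statistics and transform a dataset
#'
#' Covariates are standardized to mean 0 / unit variance (statistics stored
#' for reuse on new points); optionally the response is replaced by
#' `log(y + offset)` to tame the right skew of cover-type data. The same
#' `Preprocessor` then transforms covariates of new prediction locations
#' and back-transforms predicted responses.
#'
#' @param data A [spatial_dataset()].
#' @param log_response Apply a log transform to the response?
#' @param log_offset Offset added inside the log (default 1, i.e. log1p
#'   style, so zero responses are valid).
#' @return A list with elements `pre` (class `preprocessor`) and `data`
#'   (the transformed [spatial_dataset()]).
#' @examples
#' d <- spatial_dataset(cbind(runif(20), runif(20)), rexp(20),
#'                      matrix(rnorm(40), 20, 2))
#' pp <- preprocess_fit(d, log_response = TRUE)
#' range(colMeans(pp$data$covariates))  # ~0
#' @export
preprocess_fit <- function(data, log_response = FALSE, log_offset = 1) {
  X <- data$covariates
  p <- ncol(X)
  if (p > 0L) {
    mu <- colMeans(X)
    sigma <- apply(X, 2L, stats::sd)
    if (any(sigma == 0))
      stop("zero-variance covariate: ",
           paste(data$covariate_names[sigma == 0], collapse = ", "))
  } else {
    mu <- numeric(0); sigma <- numeric(0)
  }
  pre <- structure(list(mean = mu, sd = sigma,
                        log_response = isTRUE(log_response),
                        log_offset = log_offset,
                        feature_names = data$covariate_names),
                   class = "preprocessor")
  out <- data
  out$covariates <- pp_transform_covariates(pre, X)
  out$response <- pp_transform_response(pre, data$response)
  list(pre = pre, data = out)
}

#' @export
print.preprocessor <- function(x, ...) {
  cat("<preprocessor> ", length(x$mean), " standardized covariates; ",
      if (x$log_response) paste0("log(y + ", x$log_offset, ") response")
      else "identity response", "\n", sep = "")
  invisible(x)
}

#' Apply / invert stored preprocessing transforms
#'
#' @param pre A `preprocessor` from [preprocess_fit()].
#' @param X Covariate matrix on the original scale.
#' @return Transformed matrix / vector.
#' @export
pp_transform_covariates <- function(pre, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(pre$mean))
    stop("expected ", length(pre$mean), " covariates, got ", ncol(X))
  if (ncol(X) == 0L) return(X)
  sweep(sweep(X, 2L, pre$mean, "-"), 2L, pre$sd, "/")
}

#' @rdname pp_transform_covariates
#' @export
pp_inverse_covariates <- function(pre, X) {
  if (ncol(X) == 0L) return(as.matrix(X))
  sweep(sweep(as.matrix(X), 2L, pre$sd, "*"), 2L, pre$mean, "+")
}

#' @rdname pp_transform_covariates
#' @param y Response vector.
#' @export
pp_transform_response <- function(pre, y) {
  if (!pre$log_response) return(y)
  z <- y + pre$log_offset
  if (any(z <= 0))
    stop("log transform needs y + offset > 0; smallest value is ", min(z))
  log(z)
}

#' @rdname pp_transform_covariates
#' @export
pp_inverse_response <- function(pre, y) {
  if (!pre$log_response) return(y)
  exp(y) - pre$log_offset
}
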