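#' Construct a point-referenced spatial dataset
#'
#' The container every modelling stage consumes: `n` planar point locations,
#' a continuous response observed at each, and an optional `n x p` matrix of
#' covariates describing the locations. `p = 0` is valid and supports
#' kriging-only use.
#'
#' @param coords Numeric `n x 2` matrix (or two-column data frame) of planar
#'   coordinates. Distances are plain Euclidean on these columns.
#' @param response Numeric length-`n` response vector.
#' @param covariates Numeric `n x p` matrix of covariates, or `NULL` for
#'   `p = 0`.
#' @param covariate_names Optional length-`p` character vector of covariate
#'   labels; defaults to the matrix column names or `X1..Xp`.
#' @param allow_duplicates Logical; if `FALSE` (default) duplicated
#'   coordinate rows are an error. Duplicated locations make the ordinary
#'   kriging system singular, so they must be deduplicated (see
#'   [dedup_average()]) or explicitly permitted.
#' @return An object of class `spatial_dataset` with elements `coords`,
#'   `response`, `covariates`, `covariate_names`.
#' @examples
#' d <- spatial_dataset(cbind(runif(10), runif(10)), rnorm(10),
#'                      matrix(rnorm(30), 10, 3))
#' d
#' @export
spatial_dataset <- function(coords, response, covariates = NULL,
                            covariate_names = NULL,
                            allow_duplicates = FALSE) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2L)
    stop("`coords` must have exactly 2 columns, got ", ncol(coords))
  n <- nrow(coords)
  if (n < 1L) stop("need at least one location")
  response <- as.numeric(response)
  if (length(response) != n)
    stop("`response` length (", length(response),
         ") does not match number of locations (", n, ")")
  if (is.null(covariates)) {
    covariates <- matrix(numeric(0), nrow = n, ncol = 0L)
  } else {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
  }
  if (nrow(covariates) != n)
    stop("`covariates` must have one row per location")
  p <- ncol(covariates)
  if (is.null(covariate_names)) {
    covariate_names <- colnames(covariates)
    if (is.null(covariate_names) && p > 0L)
      covariate_names <- paste0("X", seq_len(p))
    if (p == 0L) covariate_names <- character(0)
  }
  if (length(covariate_names) != p)
    stop("`covariate_names` must have length ", p)
  colnames(covariates) <- covariate_names
  if (anyNA(coords) || anyNA(response) || anyNA(covariates))
    stop("missing values are not allowed; drop or impute incomplete rows first")
  if (!all(is.finite(coords)) || !all(is.finite(response)) ||
      (p > 0L && !all(is.finite(covariates))))
    stop("non-finite values are not allowed")
  if (!allow_duplicates && anyDuplicated(coords)) {
    dup <- which(duplicated(coords) | duplicated(coords, fromLast = TRUE))
    stop("duplicated coordinates at rows ",
         paste(utils::head(dup, 10L), collapse = ", "),
         "; deduplicate (see dedup_average()) or set allow_duplicates = TRUE")
  }
  structure(
    list(coords = coords, response = response, covariates = covariates,
         covariate_names = covariate_names),
    class = "spatial_dataset")
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat("<spatial_dataset> ", nrow(x$coords), " locations, ",
      ncol(x$covariates), " covariates\n", sep = "")
  cat("  response: mean ", signif(mean(x$response), 4),
      ", sd ", signif(stats::sd(x$response), 4), "\n", sep = "")
  if (ncol(x$covariates) > 0L)
    cat("  covariates: ",
        paste(utils::head(x$covariate_names, 8L), collapse = ", "),
        if (ncol(x$covariates) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Number of locations / covariates of a spatial dataset
#' @param data A [spatial_dataset()].
#' @return Integer count.
#' @export
n_points <- function(data) nrow(data$coords)

#' @rdname n_points
#' @export
n_covariates <- function(data) ncol(data$covariates)

#' Subset a spatial dataset by row indices
#'
#' @param data A [spatial_dataset()].
#' @param idx Integer (or logical) row index vector.
#' @return A `spatial_dataset` restricted to `idx`.
#' @export
subset_rows <- function(data, idx) {
  spatial_dataset(data$coords[idx, , drop = FALSE],
                  data$response[idx],
                  data$covariates[idx, , drop = FALSE],
                  data$covariate_names,
                  allow_duplicates = TRUE)
}

#' Average observations sharing a location
#'
#' Collapses rows with identical coordinates to a single row holding the mean
#' response and mean covariates, so that kriging systems stay nonsingular.
#'
#' @param data A [spatial_dataset()] (constructed with
#'   `allow_duplicates = TRUE`).
#' @return A deduplicated `spatial_dataset`.
#' @export
dedup_average <- function(data) {
  key <- paste(data$coords[, 1L], data$coords[, 2L], sep = "\r")
  grp <- match(key, unique(key))
  agg <- function(v) as.numeric(tapply(v, grp, mean))
  coords <- cbind(agg(data$coords[, 1L]), agg(data$coords[, 2L]))
  covs <- if (ncol(data$covariates) > 0L)
    apply(data$covariates, 2L, agg) else NULL
  if (!is.null(covs)) covs <- matrix(covs, nrow = nrow(coords),
                                     dimnames = list(NULL, data$covariate_names))
  spatial_dataset(coords, agg(data$response), covs, data$covariate_names)
}

#' Read / write point data as CSV
#'
#' CSV dialect: comma-separated, header required, UTF-8, "." decimal.
#' Rows containing `NA` are rejected unless `drop_na = TRUE`, in which case
#' incomplete rows are dropped and the count is reported via a message.
#'
#' @param path File path.
#' @param coord_cols Length-2 character vector naming the coordinate columns.
#' @param response_col Name of the response column.
#' @param covariate_cols Names of covariate columns; default: every other
#'   numeric column.
#' @param drop_na Drop incomplete rows instead of erroring.
#' @param ... Passed to [spatial_dataset()].
#' @return A [spatial_dataset()].
#' @export
read_spatial_csv <- function(path, coord_cols = c("x", "y"),
                             response_col = "y_obs",
                             covariate_cols = NULL, drop_na = FALSE, ...) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c(coord_cols, response_col)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("columns not found in ", path, ": ", paste(miss, collapse = ", "))
  if (is.null(covariate_cols))
    covariate_cols <- setdiff(names(df)[vapply(df, is.numeric, TRUE)], need)
  used <- df[, c(need, covariate_cols), drop = FALSE]
  if (anyNA(used)) {
    if (!drop_na)
      stop("input contains NA values; use drop_na = TRUE to exclude those rows")
    keep <- stats::complete.cases(used)
    message("dropped ", sum(!keep), " rows with missing values")
    used <- used[keep, , drop = FALSE]
  }
  spatial_dataset(as.matrix(used[, coord_cols]), used[[response_col]],
                  if (length(covariate_cols))
                    as.matrix(used[, covariate_cols, drop = FALSE]) else NULL,
                  covariate_names = covariate_cols, ...)
}

#' @rdname read_spatial_csv
#' @param data A [spatial_dataset()] to write.
#' @export
write_spatial_csv <- function(data, path, coord_cols = c("x", "y"),
                              response_col = "y_obs") {
  df <- data.frame(data$coords[, 1L], data$coords[, 2L], data$response,
                   check.names = FALSE)
  names(df) <- c(coord_cols, response_col)
  if (ncol(data$covariates) > 0L)
    df <- cbind(df, as.data.frame(data$covariates, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Minimum training size for trend-based hybrid models
#'
#' The rule of thumb for the smallest training sample that supports fitting a
#' regression-type trend with `p` candidate covariates: `2 * p + 20`.
#' Hybrid trend-plus-residual-kriging models trained below this size tend to
#' do no better (often worse) than plain ordinary kriging, so the hybrid
#' fitter refuses such data unless overridden.
#'
#' @param p Number of candidate covariates.
#' @return Integer minimum training size.
#' @examples
#' min_train_size(39)  # 98
#' @export
min_train_size <- function(p) {
  stopifnot(length(p) == 1L, p >= 0)
  as.integer(2L * as.integer(p) + 20L)
}

# shared Euclidean distance helpers: every kriging / variogram path goes
# through these so that identical inputs give bitwise-identical distances
euclid_to_point <- function(coords, x0) {
  sqrt((coords[, 1L] - x0[1L])^2 + (coords[, 2L] - x0[2L])^2)
}

euclid_pairs <- function(coords) {
  stats::dist(coords)  # lower-triangle vector
}
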