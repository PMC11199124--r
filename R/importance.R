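#' Relative influence of covariates in a BRT model
#'
#' For every covariate, sums the squared-error reduction of all splits made
#' on it across the whole ensemble and normalizes the scores to total 100.
#' A constant-response model (no split ever improved the fit) returns all
#' zeros with the `no_signal` attribute set.
#'
#' @param model A fitted [fit_brt()] model.
#' @return An `importance_table`: data frame with columns `variable`,
#'   `score`, `rank` (ties broken by score then name), sorted by rank.
#' @export
brt_importance <- function(model) {
  if (!inherits(model, "brt_model")) stop("expected a brt_model")
  p <- length(model$feature_names)
  raw <- numeric(p)
  for (t in model$trees) {
    splits <- t$var >= 0L
    if (any(splits)) {
      contrib <- tapply(t$improve[splits], t$var[splits] + 1L, sum)
      idx <- as.integer(names(contrib))
      raw[idx] <- raw[idx] + as.numeric(contrib)
    }
  }
  total <- sum(raw)
  score <- if (total > 0) 100 * raw / total else raw
  out <- importance_table(model$feature_names, score)
  attr(out, "no_signal") <- total <= 0
  out
}

importance_table <- function(variable, score, selected = NULL) {
  ord <- order(-score, variable)
  out <- data.frame(variable = variable[ord], score = score[ord],
                    rank = seq_along(variable))
  if (!is.null(selected)) out$selected <- selected[ord]
  class(out) <- c("importance_table", "data.frame")
  out
}

#' LASSO variable selection and ranking
#'
#' The selected set is exactly the covariates with nonzero coefficients;
#' within it, variables are ranked by absolute coefficient magnitude on the
#' standardized scale (the conventional reading of "importance" for a
#' penalized linear fit). Unselected variables carry score 0 and
#' `selected = FALSE`.
#'
#' @param model A fitted [fit_lasso()] model.
#' @return An `importance_table` with columns `variable`, `score`
#'   (|coefficient|), `rank`, `selected`.
#' @export
lasso_selection <- function(model) {
  if (!inherits(model, "lasso_model")) stop("expected a lasso_model")
  importance_table(model$feature_names, abs(as.numeric(model$coefficients)),
                   selected = model$coefficients != 0)
}

#' Importance of a hybrid model
#'
#' Variable attribution of a hybrid model derives solely from its trend
#' component: residual kriging weighs locations, not covariates.
#'
#' @param model A [fit_hybrid()] model.
#' @return The trend model's `importance_table`.
#' @export
hybrid_importance <- function(model) {
  if (!inherits(model, "hybrid_model")) stop("expected a hybrid_model")
  if (model$trend$kind == "brt") brt_importance(model$trend)
  else lasso_selection(model$trend)
}

#' @export
print.importance_table <- function(x, ...) {
  cat("<importance_table> ", nrow(x), " variables\n", sep = "")
  print.data.frame(utils::head(x, 15L), row.names = FALSE, ...)
  if (nrow(x) > 15L) cat("  ...\n")
  invisible(x)
}

#' Top-k membership frequency across datasets
#'
#' Given one importance table per dataset (e.g. per ecoregion), counts for
#' every variable how many datasets rank it within the top `k`, and returns
#' the counts in decreasing order. For LASSO-style tables only selected
#' variables are eligible for the top `k`.
#'
#' @param tables List of `importance_table`s over an identical variable
#'   universe.
#' @param k Top-rank cut (default 15).
#' @return Data frame `variable`, `frequency`, sorted by decreasing
#'   frequency (ties by name).
#' @export
topk_frequency <- function(tables, k = 15L) {
  stopifnot(length(tables) >= 1L)
  universe <- sort(tables[[1L]]$variable)
  for (i in seq_along(tables)) {
    ui <- sort(tables[[i]]$variable)
    if (!identical(ui, universe)) {
      diff <- c(setdiff(ui, universe), setdiff(universe, ui))
      stop("inconsistent variable universes across tables; ",
           "symmetric difference: ", paste(diff, collapse = ", "))
    }
  }
  counts <- stats::setNames(integer(length(universe)), universe)
  for (tab in tables) {
    elig <- tab
    if (!is.null(tab$selected)) elig <- tab[tab$selected, , drop = FALSE]
    top <- utils::head(elig$variable, k)
    counts[top] <- counts[top] + 1L
  }
  out <- data.frame(variable = names(counts), frequency = as.integer(counts))
  out[order(-out$frequency, out$variable), , drop = FALSE]
}

#' Drop named covariates from a dataset
#'
#' @param data A [spatial_dataset()].
#' @param drop Character vector of covariate names to remove (may be empty).
#' @return The reduced `spatial_dataset`.
#' @export
drop_covariates <- function(data, drop) {
  if (length(drop) == 0L) return(data)
  unknown <- setdiff(drop, data$covariate_names)
  if (length(unknown))
    stop("unknown covariate name(s): ", paste(unknown, collapse = ", "))
  keep <- setdiff(data$covariate_names, drop)
  spatial_dataset(data$coords, data$response,
                  data$covariates[, keep, drop = FALSE], keep,
                  allow_duplicates = TRUE)
}

#' Sensitivity re-run after removing covariates
#'
#' Re-runs cross-validation on the dataset with the named covariates
#' removed and reports the paired per-fold RMSE change against the
#' full-covariate baseline (shared fold partition).
#'
#' @inheritParams cross_validate
#' @param drop Covariate names to remove.
#' @param algorithms Named list as in [repeated_cv()].
#' @param ... Passed to [cross_validate()].
#' @return Data frame per algorithm: baseline and ablated pooled RMSE and
#'   their difference (`delta = ablated - baseline`; positive means the
#'   removal hurt), plus per-fold RMSE matrices in the `"folds"` attribute.
#' @export
ablation_rerun <- function(data, drop, algorithms, k = 10L, seed = 1L, ...) {
  reduced <- drop_covariates(data, drop)
  folds <- kfold_split(n_points(data), k, seed)
  algs <- sub("\\..*$", "", names(algorithms))
  base_r <- abl_r <- numeric(length(algorithms))
  fold_base <- fold_abl <- matrix(NA_real_, k, length(algorithms),
                                  dimnames = list(NULL, names(algorithms)))
  for (j in seq_along(algorithms)) {
    b <- cross_validate(data, algs[j], algorithms[[j]], folds = folds, ...)
    a <- cross_validate(reduced, algs[j], algorithms[[j]], folds = folds, ...)
    base_r[j] <- b$pooled_rmse; abl_r[j] <- a$pooled_rmse
    fold_base[, j] <- b$fold_rmse; fold_abl[, j] <- a$fold_rmse
  }
  out <- data.frame(algorithm = names(algorithms), baseline_rmse = base_r,
                    ablated_rmse = abl_r, delta = abl_r - base_r)
  attr(out, "folds") <- list(baseline = fold_base, ablated = fold_abl)
  out
}
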