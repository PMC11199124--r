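# Ordinary kriging with a local search neighborhood.
#
# The predictor at x0 is the weighted sum of the k = min(nMax, n) nearest
# observations, with weights solving the (k+1) x (k+1) system
#   [ Gamma  1 ] [ lambda ]   [ gamma0 ]
#   [ 1'     0 ] [ mu     ] = [ 1      ]
# where Gamma_ij = gamma(|x_i - x_j|) and gamma0_i = gamma(|x_i - x0|).
# The unit constraint makes the predictor unbiased under an unknown
# constant (local) mean; the prediction variance is lambda' gamma0 + mu.

# resolve (coords, values) from a spatial_dataset or a raw field list
.field_parts <- function(train) {
  if (inherits(train, "spatial_dataset"))
    list(coords = train$coords, values = train$response)
  else
    list(coords = as.matrix(train$coords), values = as.numeric(train$values))
}

# single-point kriging core shared by krige_point and krige_grid so the two
# are bitwise identical by construction
.krige_one <- function(coords, values, vm, x0, nMax) {
  n <- nrow(coords)
  d0 <- euclid_to_point(coords, x0)
  k <- min(nMax, n)
  # order() with the radix method is stable: ties at identical distance are
  # broken by ascending row index
  nb <- order(d0, method = "radix")[seq_len(k)]
  nc <- coords[nb, , drop = FALSE]
  D <- matrix(0, k, k)
  if (k > 1L) {
    D[lower.tri(D)] <- as.vector(euclid_pairs(nc))
    D <- D + t(D)
    off <- D[upper.tri(D)]
    if (any(off == 0)) {
      bad <- which(D == 0 & upper.tri(D), arr.ind = TRUE)[1L, ]
      stop("singular kriging system: neighbors at rows ",
           nb[bad[1L]], " and ", nb[bad[2L]],
           " share the same location; deduplicate the training data")
    }
  }
  # solve on a sill-normalized scale: kriging weights are invariant to a
  # constant rescaling of gamma, and normalizing keeps the system
  # well-conditioned even when the fitted sill is tiny (near-zero residual
  # fields); the variance is scaled back afterwards
  sill <- vm$nugget + vm$psill
  vmn <- vm
  if (sill > 0) {
    vmn$nugget <- vm$nugget / sill
    vmn$psill <- vm$psill / sill
  } else sill <- 1
  G <- vgm_gamma(vmn, D)
  diag(G) <- 0
  A <- rbind(cbind(G, 1), c(rep(1, k), 0))
  g0 <- vgm_gamma(vmn, d0[nb])
  b <- c(g0, 1)
  sol <- tryCatch(solve(A, b), error = function(e)
    stop("singular kriging system at target (", x0[1L], ", ", x0[2L],
         "): ", conditionMessage(e)))
  w <- sol[seq_len(k)]
  mu <- sol[k + 1L]
  v <- sill * (sum(w * g0) + mu)
  if (v < -1e-8)
    stop("negative kriging variance (", v, ") at target (",
         x0[1L], ", ", x0[2L], ")")
  if (v < 0) v <- 0
  list(value = sum(w * values[nb]), variance = v, weights = w,
       neighbor_indices = nb)
}

#' Ordinary kriging prediction at a single location
#'
#' Predicts the field at `x0` from the `min(nMax, n)` nearest training
#' points (Euclidean distance, ties broken by ascending row index) by
#' solving the ordinary-kriging system with a Lagrange multiplier. Weights
#' sum to one, making the predictor unbiased under a locally constant
#' unknown mean; with a zero nugget the predictor interpolates the training
#' data exactly.
#'
#' @param train A [spatial_dataset()], or a list with `coords` and `values`
#'   (e.g. a trend-residual field).
#' @param vm A fitted [variogram_model()].
#' @param x0 Length-2 numeric target location.
#' @param nMax Search-window size: the number of nearest observations
#'   entering the local kriging system.
#' @return An object of class `kriging_prediction`: list with `value`,
#'   `variance` (>= 0), `weights` (sum to 1), `neighbor_indices`.
#' @examples
#' tr <- spatial_dataset(cbind(c(0, 1), c(0, 0)), c(0, 2))
#' vm <- variogram_model(0, 1, 1)
#' krige_point(tr, vm, c(0.5, 0), nMax = 2)
#' @export
krige_point <- function(train, vm, x0, nMax) {
  fp <- .field_parts(train)
  stopifnot(length(x0) == 2L, is.finite(x0))
  if (nMax < 1L) stop("nMax must be >= 1")
  out <- .krige_one(fp$coords, fp$values, vm, as.numeric(x0), nMax)
  class(out) <- "kriging_prediction"
  out
}

#' @export
print.kriging_prediction <- function(x, ...) {
  cat(sprintf("<kriging_prediction> value %.6g, variance %.6g, k = %d\n",
              x$value, x$variance, length(x$weights)))
  invisible(x)
}

#' Ordinary kriging over a set of target locations
#'
#' Elementwise identical to [krige_point()] at each row of `targets` (the
#' same core routine is called per point).
#'
#' @inheritParams krige_point
#' @param targets `m x 2` matrix of target locations.
#' @return A data frame with columns `value` and `variance`, one row per
#'   target.
#' @export
krige_grid <- function(train, vm, targets, nMax) {
  fp <- .field_parts(train)
  targets <- as.matrix(targets)
  if (ncol(targets) != 2L) stop("`targets` must have 2 columns")
  m <- nrow(targets)
  value <- numeric(m); variance <- numeric(m)
  for (i in seq_len(m)) {
    res <- tryCatch(
      .krige_one(fp$coords, fp$values, vm, targets[i, ], nMax),
      error = function(e)
        stop("kriging failed at target ", i, ": ", conditionMessage(e)))
    value[i] <- res$value
    variance[i] <- res$variance
  }
  data.frame(value = value, variance = variance)
}
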