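#' Spherical variogram model
#'
#' Holds the three parameters of the spherical semivariogram
#' \deqn{\gamma(h) = c_0 + c_1\,(1.5\,h/a - 0.5\,(h/a)^3)} for
#' \eqn{0 < h \le a} and \eqn{\gamma(h) = c_0 + c_1} for \eqn{h > a}, with
#' \eqn{\gamma(0) = 0} by convention (the nugget applies only for h > 0).
#'
#' @param nugget Nugget variance \eqn{c_0 \ge 0}: micro-scale plus
#'   measurement variance.
#' @param psill Partial sill \eqn{c_1 \ge 0}: spatially structured variance.
#' @param range Range \eqn{a > 0}: the distance at which spatial correlation
#'   vanishes, in coordinate units.
#' @return An object of class `variogram_model`.
#' @examples
#' vm <- variogram_model(nugget = 0.1, psill = 1, range = 0.3)
#' vgm_gamma(vm, c(0, 0.15, 0.3, 1))
#' @export
variogram_model <- function(nugget, psill, range) {
  stopifnot(is.finite(nugget), is.finite(psill), is.finite(range))
  if (nugget < 0) stop("nugget must be >= 0")
  if (psill < 0) stop("partial sill must be >= 0")
  if (range <= 0) stop("range must be > 0")
  structure(list(nugget = nugget, psill = psill, range = range,
                 model_name = "spherical"),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model> spherical: nugget %.6g, psill %.6g, range %.6g (sill %.6g)\n",
              x$nugget, x$psill, x$range, x$nugget + x$psill))
  invisible(x)
}

#' Evaluate a spherical semivariogram
#'
#' @param vm A [variogram_model()].
#' @param h Nonnegative distances (vector or matrix; shape preserved).
#' @return Semivariance \eqn{\gamma(h)}, 0 exactly at h = 0.
#' @export
vgm_gamma <- function(vm, h) {
  r <- pmin(h / vm$range, 1)
  g <- vm$nugget + vm$psill * (1.5 * r - 0.5 * r^3)
  g[h == 0] <- 0
  if (is.matrix(h)) dim(g) <- dim(h)
  g
}

#' Covariance function implied by a spherical variogram
#'
#' `C(h) = (c0 + c1) - gamma(h)` for h > 0 and `c0 + c1` at h = 0; used by
#' the Gaussian-random-field simulator.
#'
#' @inheritParams vgm_gamma
#' @return Covariances with the shape of `h`.
#' @export
vgm_cov <- function(vm, h) {
  (vm$nugget + vm$psill) - vgm_gamma(vm, h)
}

#' Empirical semivariogram (Matheron estimator)
#'
#' Bins all point pairs within `cutoff` by separation distance and computes
#' the classical method-of-moments estimate per bin:
#' \deqn{\hat\gamma(h_b) = \frac{1}{2 |N(h_b)|} \sum_{(i,j) \in N(h_b)} (y_i - y_j)^2.}
#' Bins containing no pairs are dropped; the reported lag of a bin is the
#' mean separation of its pairs. Pairs at distance zero (duplicate
#' locations) are excluded: the semivariogram is defined for h > 0.
#'
#' @param data A [spatial_dataset()], or a list with elements `coords`
#'   (n x 2 matrix) and `values` (length-n vector) for an arbitrary field
#'   such as trend residuals.
#' @param n_bins Number of equal-width distance bins (default 15).
#' @param cutoff Maximum separation considered; default one-third of the
#'   maximum pairwise distance.
#' @return An object of class `empirical_variogram`: a data frame with
#'   columns `lag` (mean pair distance per bin), `gamma`, `np` (pair count),
#'   and attributes `cutoff`, `n_bins`.
#' @export
empirical_variogram <- function(data, n_bins = 15L, cutoff = NULL) {
  if (inherits(data, "spatial_dataset")) {
    coords <- data$coords; values <- data$response
  } else {
    coords <- as.matrix(data$coords); values <- as.numeric(data$values)
  }
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 points to estimate a variogram")
  if (length(values) != n) stop("values/coords length mismatch")
  d <- as.vector(euclid_pairs(coords))
  if (is.null(cutoff)) cutoff <- max(d) / 3
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  keep <- d <= cutoff & d > 0
  if (!any(keep)) stop("no lag pairs: all point pairs lie beyond the cutoff")
  dv <- as.vector(stats::dist(matrix(values, ncol = 1L)))  # |y_i - y_j|
  d <- d[keep]; dv <- dv[keep]
  breaks <- seq(0, cutoff, length.out = n_bins + 1L)
  bin <- findInterval(d, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  np <- tabulate(bin, nbins = n_bins)
  sq <- dv^2
  gsum <- vapply(seq_len(n_bins), function(b) sum(sq[bin == b]), 0)
  hbar <- vapply(seq_len(n_bins), function(b) sum(d[bin == b]), 0)
  nz <- np > 0L
  out <- data.frame(lag = hbar[nz] / np[nz],
                    gamma = gsum[nz] / (2 * np[nz]),
                    np = np[nz])
  structure(out, cutoff = cutoff, n_bins = as.integer(n_bins),
            class = c("empirical_variogram", "data.frame"))
}

#' @export
print.empirical_variogram <- function(x, ...) {
  cat("<empirical_variogram> ", nrow(x), " bins, cutoff ",
      signif(attr(x, "cutoff"), 4), "\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

# spherical shape function g(h; a) so that gamma = c0 + c1 * g, g(0+)=0,
# g(h>=a)=1; used by the profiled WLS fit
sph_shape <- function(h, a) {
  r <- pmin(h / a, 1)
  1.5 * r - 0.5 * r^3
}

# constrained WLS solve of gamma_hat ~ c0 + c1 * g with c0, c1 >= 0 and
# weights w; closed-form 2x2 with nonnegativity by case analysis
wls_c0c1 <- function(g, gam, w) {
  sw <- sum(w); sg <- sum(w * g); sgg <- sum(w * g * g)
  sy <- sum(w * gam); sgy <- sum(w * g * gam)
  det <- sw * sgg - sg * sg
  if (det > 1e-300) {
    c0 <- (sgg * sy - sg * sgy) / det
    c1 <- (sw * sgy - sg * sy) / det
  } else c0 <- c1 <- -1
  if (c0 < 0 || c1 < 0 || det <= 1e-300) {
    # boundary candidates: c0 = 0, or c1 = 0
    c1a <- if (sgg > 0) max(sgy / sgg, 0) else 0
    c0b <- max(sy / sw, 0)
    ssa <- sum(w * (gam - c1a * g)^2)
    ssb <- sum(w * (gam - c0b)^2)
    if (ssa <= ssb) { c0 <- 0; c1 <- c1a } else { c0 <- c0b; c1 <- 0 }
  }
  c(c0, c1)
}

#' Fit a spherical model to an empirical variogram
#'
#' Weighted least squares with the pair-count weighting
#' \eqn{w_b = N_b / h_b^2}: minimizes
#' \eqn{\sum_b w_b (\hat\gamma_b - \gamma(h_b; c_0, c_1, a))^2} subject to
#' \eqn{c_0, c_1 \ge 0, a > 0}. Because the spherical model is linear in
#' \eqn{(c_0, c_1)} given the range, the fit profiles out the linear part in
#' closed form and searches the range over a deterministic grid refined by
#' golden-section optimisation, which is robust to the multimodality of the
#' WLS surface.
#'
#' @param ev An [empirical_variogram()] with at least 3 nonempty bins.
#' @param init Optional [variogram_model()]; its range is added to the
#'   candidate grid.
#' @param range_grid_size Number of candidate ranges scanned (default 100).
#' @return A [variogram_model()].
#' @export
fit_spherical <- function(ev, init = NULL, range_grid_size = 100L) {
  if (nrow(ev) < 3L)
    stop("need at least 3 nonempty variogram bins, got ", nrow(ev))
  h <- ev$lag; gam <- ev$gamma
  if (all(gam == 0))
    stop("degenerate empirical variogram: all semivariances are zero ",
         "(constant field?)")
  w <- ev$np / h^2
  a_lo <- 1e-6 * max(h)
  a_hi <- 2 * max(h)
  grid <- c(a_lo, exp(seq(log(min(h) / 4), log(a_hi),
                          length.out = range_grid_size)))
  if (!is.null(init)) grid <- c(grid, init$range)
  obj <- function(a) {
    cc <- wls_c0c1(sph_shape(h, a), gam, w)
    sum(w * (gam - cc[1L] - cc[2L] * sph_shape(h, a))^2)
  }
  ss <- vapply(grid, obj, 0)
  best <- which.min(ss)  # ties -> earliest candidate (a_lo first): deterministic
  a_star <- grid[best]
  # local refinement around the best grid point
  lo <- if (best > 1L) min(grid[best], grid[best - 1L]) else a_lo
  hi <- if (best < length(grid)) max(grid[best], grid[best + 1L]) else a_hi
  if (hi > lo) {
    op <- stats::optimize(obj, c(lo, hi), tol = 1e-10)
    if (op$objective < ss[best]) a_star <- op$minimum
  }
  cc <- wls_c0c1(sph_shape(h, a_star), gam, w)
  if (!all(is.finite(cc)) || cc[1L] + cc[2L] <= 0)
    stop("spherical variogram fit failed: degenerate solution (c0 + c1 = ",
         cc[1L] + cc[2L], ")")
  variogram_model(nugget = cc[1L], psill = cc[2L],
                  range = max(a_star, a_lo))
}

#' Serialize / restore a fitted variogram model
#'
#' A small key-value JSON block (`model_name`, `nugget`, `psill`, `range`)
#' for provenance alongside run outputs.
#'
#' @param vm A [variogram_model()].
#' @param path Output (input) file path.
#' @return `path` (invisibly) / a [variogram_model()].
#' @export
write_variogram_json <- function(vm, path) {
  jsonlite::write_json(unclass(vm), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_variogram_json
#' @export
read_variogram_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  variogram_model(x$nugget, x$psill, x$range)
}
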