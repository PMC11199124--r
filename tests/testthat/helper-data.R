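# fixture builders used across test files; everything is generated in code

# small irregular point set with a smooth response, no randomness
toy_dataset <- function(n = 25) {
  g <- ceiling(sqrt(n))
  xy <- expand.grid(x = seq(0, 1, length.out = g),
                    y = seq(0, 1, length.out = g))[seq_len(n), ]
  coords <- as.matrix(xy) + 0.01 * sin(seq_len(n))  # break exact collinearity
  resp <- sin(3 * coords[, 1]) + coords[, 2]^2
  spatial_dataset(coords, resp)
}

random_dataset <- function(n = 60, p = 3, seed = 1) {
  set.seed(seed)
  spatial_dataset(cbind(runif(n), runif(n)), rnorm(n),
                  matrix(rnorm(n * p), n, p))
}

# independent spherical semivariogram (kept separate from the package's
# vgm_gamma on purpose: oracle code must not share the implementation)
sph_gamma_oracle <- function(h, c0, c1, a) {
  ifelse(h == 0, 0,
         ifelse(h >= a, c0 + c1,
                c0 + c1 * (1.5 * h / a - 0.5 * (h / a)^3)))
}

# dense global ordinary-kriging solve: the full (n+1) system, no
# neighborhood restriction
global_ok_oracle <- function(coords, values, c0, c1, a, x0) {
  n <- nrow(coords)
  D <- as.matrix(dist(coords))
  G <- sph_gamma_oracle(D, c0, c1, a)
  diag(G) <- 0
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  d0 <- sqrt((coords[, 1] - x0[1])^2 + (coords[, 2] - x0[2])^2)
  b <- c(sph_gamma_oracle(d0, c0, c1, a), 1)
  sol <- solve(A, b)
  list(value = sum(sol[1:n] * values),
       variance = unname(sum(sol[1:n] * b[1:n]) + sol[n + 1]),
       weights = unname(sol[1:n]))
}

# evaluate a fitted BRT ensemble tree by tree in R (0-based node records)
brt_oracle_predict <- function(model, X) {
  eval_tree <- function(t, x) {
    node <- 1L
    while (t$var[node] >= 0L) {
      node <- if (x[t$var[node] + 1L] <= t$split[node])
        t$left[node] + 1L else t$right[node] + 1L
    }
    t$value[node]
  }
  pred <- rep(model$init, nrow(X))
  for (t in model$trees)
    pred <- pred + model$config$learning_rate *
      apply(X, 1L, function(x) eval_tree(t, x))
  pred
}

# exhaustive best-stump search: all features, all midpoints between
# adjacent distinct sorted values, min_obs per side
best_stump_oracle <- function(X, r, min_obs = 1L) {
  n <- length(r)
  best <- list(imp = 0, var = NA, split = NA)
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[, j]))
    if (length(xs) < 2) next
    for (s in (xs[-1] + xs[-length(xs)]) / 2) {
      L <- X[, j] <= s
      if (sum(L) < min_obs || sum(!L) < min_obs) next
      imp <- sum(r[L])^2 / sum(L) + sum(r[!L])^2 / sum(!L) - sum(r)^2 / n
      if (imp > best$imp) best <- list(imp = imp, var = j, split = s)
    }
  }
  best
}
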