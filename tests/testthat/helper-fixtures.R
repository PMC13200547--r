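# shared helpers for the test suite

# prox objective value for a scalar candidate
prox_objective <- function(spec, x, z, scale) {
  scale * penalty_value(spec, x) + (x - z)^2 / 2
}

# |prox - oracle| comparison that accepts either minimizer at non-convex
# thresholds (where the zero and nonzero solutions tie in objective)
prox_agrees <- function(spec, z, scale, p, o, tol = 1e-4, obj_tol = 1e-8) {
  if (abs(p - o) <= tol) return(TRUE)
  abs(prox_objective(spec, p, z, scale) -
      prox_objective(spec, o, z, scale)) <= obj_tol
}

# small dense regression problem with sparse truth
make_lasso_problem <- function(n = 50, p = 100, k = 5, sd = 0.5, seed = 11) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- c(rnorm(k, sd = 2), rep(0, p - k))[sample.int(p)]
  y <- as.vector(X %*% beta) + rnorm(n, sd = sd)
  list(X = X, y = y, beta = beta)
}

# (C, L, B) tensor from a samples-by-markers matrix
to_tensor_test <- function(X) genoprox:::to_tensor(X)

# standardize helper used by several fixtures
split_standardize <- function(G, y, train, test) {
  sz <- fit_standardizer(G[train, , drop = FALSE])
  ysd <- stats::sd(y[train])
  list(
    Xtr = apply_standardizer(sz, G[train, , drop = FALSE]),
    Xte = apply_standardizer(sz, G[test, , drop = FALSE]),
    ytr = (y[train] - mean(y[train])) / ysd,
    yte = (y[test] - mean(y[train])) / ysd
  )
}
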