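test_that("penalty_spec validates its parameters", {
  expect_error(penalty_spec("l1", -1), "non-negative")
  expect_error(penalty_spec("scad", 1, scad_a = 2), "> 2")
  expect_error(penalty_spec("mcp", 1, mcp_gamma = 1), "> 1")
  expect_error(penalty_spec("l5", 1))
  expect_s3_class(penalty_spec("L1", 0), "penalty_spec")  # case-insensitive
})

test_that("penalty_value matches hand computations", {
  expect_equal(penalty_value(penalty_spec("l1", 1), c(1, -2, 0)), 3)
  expect_equal(penalty_value(penalty_spec("l0", 2), c(0, 3, 0, -1)), 4)
  expect_equal(penalty_value(penalty_spec("linf", 0.5), c(3, -4)), 2)
  expect_equal(penalty_value(penalty_spec("l2", 2), c(1, 2)), 10)
  expect_error(penalty_value(penalty_spec("l1", 1), c(1, NA)), "finite")
})

test_that("scalar prox reproduces the derived closed-form values", {
  sp <- penalty_spec
  expect_equal(prox_scalar(sp("l1", 1), 3), 2)
  expect_equal(prox_scalar(sp("l1", 1), 0.5), 0)
  expect_equal(prox_scalar(sp("l0", 0.5), 1.1), 1.1)
  expect_equal(prox_scalar(sp("l0", 0.5), 0.9), 0)
  expect_equal(prox_scalar(sp("l0", 0.5), 1.0), 0)  # tie -> sparser
  expect_equal(prox_scalar(sp("l2", 0.5), 1), 0.5)
  expect_equal(prox_scalar(sp("l1/2", 1), 2), 1.6053, tolerance = 1e-3)
  expect_equal(prox_scalar(sp("l1/2", 1), 1.4), 0)
  expect_equal(prox_scalar(sp("l2/3", 1), 2), 1.4047, tolerance = 1e-2)
  expect_equal(prox_scalar(sp("l4/3", 1), 2), 0.7752, tolerance = 1e-3)
  expect_equal(prox_scalar(sp("l3/2", 1), 2), 0.7238, tolerance = 1e-3)
  expect_equal(prox_scalar(sp("l3", 1), 2), 2 / 3)
  expect_equal(prox_scalar(sp("l4", 1), 2), 0.6894, tolerance = 1e-3)
  expect_equal(prox_scalar(sp("scad", 1), 1.5), 0.5)
  expect_equal(prox_scalar(sp("scad", 1), 3), 4.4 / 1.7)
  expect_equal(prox_scalar(sp("scad", 1), 5), 5)
  expect_equal(prox_scalar(sp("mcp", 1), 2), 1.5)
  expect_equal(prox_scalar(sp("mcp", 1), 0.8), 0)
  expect_equal(prox_scalar(sp("mcp", 1), 4), 4)
  # lambda = 0 is the identity; z = 0 is a fixed point
  for (k in setdiff(penalty_kinds(), "linf")) {
    expect_equal(prox_scalar(sp(k, 0), 1.7), 1.7)
    expect_identical(prox_scalar(sp(k, 2), 0), 0)
  }
  expect_error(prox_scalar(sp("linf", 1), 1), "prox_linf")
  expect_error(prox_scalar(sp("l1", 1), 1, scale = 0), "positive")
})

test_that("elementwise prox decomposes per coordinate with its own scale", {
  sp <- penalty_spec("l1", 1)
  expect_equal(prox_elementwise(sp, c(3, 3), c(1, 0.25)), c(2, 2.75))
  expect_equal(prox_elementwise(penalty_spec("l2", 0.5), c(1, -2)),
               c(0.5, -1))
  z <- numeric(5)
  for (k in setdiff(penalty_kinds(), "linf"))
    expect_identical(prox_elementwise(penalty_spec(k, 1.3), z), z)
  m <- matrix(c(3, -3, 0.5, 0), 2, 2)
  out <- prox_elementwise(sp, m)
  expect_identical(dim(out), dim(m))
  expect_identical(out[2, 2], 0)  # bit-exact zero
  expect_error(prox_elementwise(sp, c(1, 2), c(1, 2, 3)), "length")
  expect_error(prox_elementwise(penalty_spec("linf", 1), c(1, 2)),
               "prox_linf")
})

test_that("max-norm prox clamps at the exact level and obeys Moreau", {
  expect_equal(prox_linf(1, c(3, 1)), c(2, 1))
  expect_equal(prox_linf(1, c(0.3, -0.2)), c(0, 0))
  expect_equal(prox_linf(1, 3), 2)  # dim 1 reduces to soft thresholding
  expect_error(prox_linf(1, numeric(0)), "nonempty")
  expect_error(prox_linf(1, c(1, 2), weights = c(1, 0)), "positive")
  # weighted case agrees with direct numerical minimization
  set.seed(5)
  for (i in 1:20) {
    z <- rnorm(4, sd = 2)
    w <- runif(4, 0.2, 2)
    l <- runif(1, 0.1, 2)
    p <- prox_linf(l, z, w)
    f <- function(s) l * s + sum(w * pmax(abs(z) - s, 0)^2) / 2
    s_opt <- optimize(f, c(0, max(abs(z))), tol = 1e-12)$minimum
    expect_equal(p, pmin(pmax(z, -s_opt), s_opt), tolerance = 1e-6)
  }
  # Moreau: prox + L1-ball projection reconstructs z (spot check; the full
  # sweep lives in the acceptance suite)
  set.seed(6)
  z <- rnorm(20)
  p <- prox_linf(1.5, z)
  proj <- z - p
  expect_lte(sum(abs(proj)), 1.5 + 1e-10)
  expect_equal(p + proj, z)
})

test_that("brute-force oracle finds the grid minimizer", {
  sp <- penalty_spec("l1", 1)
  expect_equal(prox_oracle_scalar(sp, 3), 2, tolerance = 1e-3)
  expect_identical(prox_oracle_scalar(penalty_spec("l0", 0.5), 0.9), 0)
  expect_equal(prox_oracle_scalar(penalty_spec("l1", 0), 1.7), 1.7,
               tolerance = 1e-3)
  expect_error(prox_oracle_scalar(sp, 1, coarse_step = 0), "> 0")
})

test_that("prox is shrinking, sign-preserving, and monotone in lambda", {
  set.seed(42)
  for (k in penalty_kinds()) {
    z <- runif(200, -5, 5)
    lam <- runif(200, 0.01, 3)
    sc <- runif(200, 0.1, 2)
    p <- vapply(seq_along(z), function(i) {
      if (k == "linf") prox_linf(lam[i] * sc[i], z[i])
      else prox_scalar(penalty_spec(k, lam[i]), z[i], sc[i])
    }, numeric(1))
    expect_true(all(abs(p) <= abs(z) + 1e-12), info = k)
    expect_true(all(sign(p) %in% c(0, sign(z)) | p == 0), info = k)
    # monotone in lambda for fixed z > 0
    lams <- seq(0.05, 3, length.out = 30)
    pz <- vapply(lams, function(l) {
      if (k == "linf") prox_linf(l, 2.3) else
        prox_scalar(penalty_spec(k, l), 2.3)
    }, numeric(1))
    expect_true(all(diff(pz) <= 1e-10), info = k)
  }
})

test_that("thresholding kinds return bit-exact zeros; power kinds never do", {
  thresh <- c("l0", "l1/2", "l2/3", "l1", "scad", "mcp")
  for (k in thresh) {
    p <- prox_scalar(penalty_spec(k, 2), 0.05)
    expect_identical(p, 0, info = k)
  }
  for (k in c("l4/3", "l3/2", "l2", "l3", "l4")) {
    p <- prox_scalar(penalty_spec(k, 5), 0.05)
    expect_gt(abs(p), 0, label = k)
  }
})
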