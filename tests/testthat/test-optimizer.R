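test_that("first step matches the hand-evaluated update formulas", {
  p <- list(w = 0)
  g <- list(w = 1)
  st <- opt_state_init(p)
  cfg <- opt_config(alpha = 0.01, beta1 = 0.1, beta2 = 0.999,
                    bias_correction = FALSE)
  r <- opt_step(st, p, g, cfg)
  # m1 = 0.9, C1 = sqrt(0.001); theta1 = -0.01 * 0.9 / (C1 + 1e-8)
  expect_equal(r$params$w, -0.01 * 0.9 / (sqrt(0.001) + 1e-8))
  expect_equal(r$params$w, -0.284605, tolerance = 1e-5)
  expect_identical(r$state$t, 1L)
  # bias correction cancels the (1 - beta) factors on the first step
  cfg2 <- opt_config(alpha = 0.01, beta1 = 0.1, beta2 = 0.999)
  r2 <- opt_step(st, p, g, cfg2)
  expect_equal(r2$params$w, -0.01, tolerance = 1e-6)
})

test_that("lambda = 0 penalty reproduces the pure adaptive-gradient path", {
  set.seed(3)
  p0 <- list(a = matrix(rnorm(6), 2, 3), b = rnorm(2))
  cfg <- opt_config(alpha = 0.05)
  run <- function(pen) {
    p <- p0; st <- opt_state_init(p)
    for (i in 1:20) {
      g <- lapply(p, function(x) 2 * x)   # grad of sum of squares
      u <- opt_step(st, p, g, cfg, penalty = pen)
      p <- u$params; st <- u$state
    }
    p
  }
  expect_identical(run(NULL), run(penalty_spec("l1", 0)))
})

test_that("zero gradient with zero state and no penalty is a fixed point", {
  p <- list(w = c(1, -2, 3))
  st <- opt_state_init(p)
  r <- opt_step(st, p, list(w = numeric(3)), opt_config(alpha = 0.1))
  expect_identical(r$params$w, p$w)
})

test_that("large-lambda thresholding zeroes all penalized weights in one step", {
  set.seed(8)
  p <- list(w = rnorm(20), bias = rnorm(3))
  st <- opt_state_init(p)
  r <- opt_step(st, p, list(w = rnorm(20), bias = rnorm(3)),
                opt_config(alpha = 0.01),
                penalty = penalty_spec("l1", 1e6), penalized = "w")
  expect_identical(r$params$w, rep(0, 20))
  expect_false(any(r$params$bias == 0))   # unpenalized arrays untouched by prox
})

test_that("invalid gradients are rejected with the parameter named", {
  p <- list(w = 1:3 / 10, v = 1)
  st <- opt_state_init(p)
  cfg <- opt_config(alpha = 0.1)
  expect_error(opt_step(st, p, list(w = c(1, NaN, 1), v = 0), cfg), "`w`")
  expect_error(opt_step(st, p, list(w = c(1, 2), v = 0), cfg), "mismatch")
  expect_error(opt_step(st, p, list(w = 1:3), cfg), "missing gradients")
})

test_that("identical configuration and data replay bit-identically", {
  run <- function() {
    set.seed(99)
    p <- list(w = rnorm(10))
    st <- opt_state_init(p)
    cfg <- opt_config(alpha = 0.02, beta1 = 0.1)
    spec <- penalty_spec("l1/2", 0.3)
    for (i in 1:50) {
      g <- list(w = 2 * p$w + rnorm(10))
      u <- opt_step(st, p, g, cfg, spec)
      p <- u$params; st <- u$state
    }
    p$w
  }
  expect_identical(run(), run())
})

test_that("full objective adds the penalty on penalized arrays only", {
  loss2 <- function(params) 2
  expect_equal(full_objective(loss2, list(w = numeric(4)),
                              penalty_spec("l1", 3)), 2)
  expect_equal(full_objective(function(p) 0, list(w = c(1, -1)),
                              penalty_spec("l1", 1)), 2)
  expect_equal(full_objective(loss2, list(w = c(1, -1), b = 5),
                              penalty_spec("l1", 1), penalized = "w"), 4)
})

test_that("prox-gradient optimization matches the coordinate-descent lasso", {
  skip_if_not_installed("glmnet")
  prob <- make_lasso_problem()
  lam <- 0.1
  spec <- penalty_spec("l1", lam)
  gl <- glmnet::glmnet(prob$X, prob$y, lambda = lam, standardize = FALSE,
                       intercept = FALSE, thresh = 1e-14)
  wg <- as.vector(stats::coef(gl))[-1]
  obj <- function(w) sum((prob$y - prob$X %*% w)^2) / (2 * nrow(prob$X)) +
    lam * sum(abs(w))
  params <- list(w = rep(0, ncol(prob$X)))
  st <- opt_state_init(params)
  cfg <- opt_config(alpha = 0.02, beta1 = 0.1)
  for (i in 1:2000) {
    g <- as.vector(crossprod(prob$X, prob$X %*% params$w - prob$y)) /
      nrow(prob$X)
    u <- opt_step(st, params, list(w = g), cfg, spec)
    params <- u$params; st <- u$state
  }
  expect_lt(abs(obj(params$w) - obj(wg)) / obj(wg), 1e-3)
})
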