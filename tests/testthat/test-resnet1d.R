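test_that("weighted-layer accounting is exact for the catalog depths", {
  expected <- list(
    "5"  = list(block = "basic", n_stem = 2L, n_blocks = 1L),
    "10" = list(block = "basic", n_stem = 1L, n_blocks = 4L),
    "15" = list(block = "basic", n_stem = 2L, n_blocks = 6L),
    "18" = list(block = "basic", n_stem = 1L, n_blocks = 8L),
    "20" = list(block = "bottleneck", n_stem = 1L, n_blocks = 6L),
    "25" = list(block = "bottleneck", n_stem = 3L, n_blocks = 7L))
  for (d in names(expected)) {
    pl <- depth_to_plan(as.integer(d))
    expect_identical(pl$block, expected[[d]]$block, info = d)
    expect_identical(pl$n_stem, expected[[d]]$n_stem, info = d)
    expect_identical(pl$n_blocks, expected[[d]]$n_blocks, info = d)
    expect_identical(pl$weighted_layers, as.integer(d), info = d)
  }
  expect_error(depth_to_plan(3), ">= 4")
  # earlier stages receive the remainder; transitions use stride 2
  pl <- depth_to_plan(15)
  expect_identical(pl$stage_blocks, c(2L, 2L, 1L, 1L))
  expect_identical(pl$stage_widths, c(16L, 32L, 64L, 128L))
  expect_identical(vapply(pl$block_strides, `[`, 1L, 1L), c(1L, 2L, 2L, 2L))
})

test_that("parameter count matches an independent hand count from the plan", {
  # depth 5, base width 4, kernel 1: stems 1->4 and 4->4 (+BN), one basic
  # block 4->4 with two convs (+2 BN), fc 4 + 1
  count <- function(bw) {
    stem <- (1 * bw * 1 + 2 * bw) + (bw * bw * 1 + 2 * bw)
    block <- 2 * (bw * bw * 1 + 2 * bw)
    stem + block + bw + 1
  }
  expect_equal(resnet_param_count(resnet_config(5, base_width = 4)),
               count(4))
  expect_equal(resnet_param_count(resnet_config(5, base_width = 16)),
               count(16))
  # kernel 3 multiplies only conv weight tensors
  c3 <- resnet_config(5, base_width = 4, kernel_size = 3)
  expect_equal(resnet_param_count(c3),
                   (1 * 4 * 3 + 8) + (4 * 4 * 3 + 8) + 2 * (4 * 4 * 3 + 8) +
                     4 + 1)
})

test_that("building is deterministic and forward output has the right shape", {
  cfg <- resnet_config(depth = 5, base_width = 4, seed = 3)
  m1 <- build_resnet1d(cfg)
  m2 <- build_resnet1d(cfg)
  expect_identical(m1$params, m2$params)
  X <- matrix(0, 3, 64)
  f1 <- resnet1d(X, rnorm(3), config = cfg, epochs = 1, batch_size = 3,
                 seed = 7)
  expect_length(predict(f1, X), 3)
  expect_true(all(is.finite(predict(f1, X))))
})

test_that("zeroed block weights make the residual block an identity", {
  cfg <- resnet_config(depth = 5, base_width = 4, seed = 2)
  m <- build_resnet1d(cfg)
  p <- m$params
  for (nm in grep("^s1b1.*\\.W$", names(p), value = TRUE)) p[[nm]][] <- 0
  set.seed(1)
  x <- to_tensor_test(matrix(rnorm(3 * 16), 3, 16))
  # run the stem by hand, then check the block output equals its input
  h <- x
  for (st in m$arch$stems) {
    cv <- genoprox:::conv_fwd(h, p[[paste0(st$name, ".W")]], 1L)
    b <- genoprox:::bn_fwd(cv$y, p[[paste0(st$name, ".bn.g")]],
                           p[[paste0(st$name, ".bn.b")]],
                           m$bn[[paste0(st$name, ".bn")]], TRUE)
    h <- genoprox:::relu_fwd(b$y)$y
  }
  fw <- genoprox:::net_fwd(m, p, m$bn, x, training = TRUE)
  # with branch weights zero the pooled features are the pooled shortcut
  pooled_shortcut <- apply(h, c(1, 3), mean)
  expect_equal(fw$caches$pooled, pooled_shortcut, tolerance = 1e-12)
})

test_that("analytic gradients agree with numerical differentiation", {
  for (cfg in list(resnet_config(depth = 5, base_width = 3, kernel_size = 3,
                                 seed = 9),
                   resnet_config(depth = 20, base_width = 2, seed = 5))) {
    m <- build_resnet1d(cfg)
    set.seed(4)
    X <- matrix(rnorm(6 * 24), 6, 24)
    y <- rnorm(6)
    lossfn <- function(params)
      mean((genoprox:::net_fwd(m, params, m$bn, to_tensor_test(X),
                               TRUE)$pred - y)^2)
    fw <- genoprox:::net_fwd(m, m$params, m$bn, to_tensor_test(X), TRUE)
    gr <- genoprox:::net_bwd(m, m$params, fw$caches, 2 * (fw$pred - y) / 6)
    eps <- 1e-5
    for (nm in names(m$params)) {
      for (i in seq_len(min(length(m$params[[nm]]), 3))) {
        pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
        num <- (lossfn(pp) - lossfn(pm)) / (2 * eps)
        expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                     label = paste(cfg$depth, nm, i))
      }
    }
  }
})

test_that("huge lambda zeroes every penalized weight; predictions constant", {
  set.seed(10)
  X <- matrix(rnorm(40 * 32), 40, 32)
  y <- rnorm(40)
  fit <- resnet1d(X, y, depth = 5, penalty = "l1", lambda = 1e6, epochs = 2,
                  batch_size = 20, seed = 1)
  expect_identical(fit$zero_fraction, 1)
  pred <- predict(fit, X)
  expect_lt(diff(range(pred)), 1e-10)
})

test_that("training traces are recorded and reproducible", {
  set.seed(11)
  X <- matrix(rnorm(120 * 64), 120, 64)
  y <- rnorm(120)
  val <- list(x = X[1:20, ], y = y[1:20])
  fit <- resnet1d(X, y, depth = 5, penalty = "l1/2", lambda = 0.1,
                  epochs = 3, batch_size = 60, validation = val, seed = 5)
  expect_identical(nrow(fit$trace), 3L)
  expect_true(all(is.finite(fit$trace$train_mse)))
  expect_true(all(is.finite(fit$trace$val_mse)))
  fit2 <- resnet1d(X, y, depth = 5, penalty = "l1/2", lambda = 0.1,
                   epochs = 3, batch_size = 60, validation = val, seed = 5)
  expect_identical(fit$model$params, fit2$model$params)
  expect_identical(fit$trace, fit2$trace)
})

test_that("inputs shorter than the stride plan are rejected", {
  cfg <- resnet_config(depth = 15)   # 4 stages, 3 stride-2 transitions
  X <- matrix(rnorm(10 * 4), 10, 4)
  expect_error(resnet1d(X, rnorm(10), config = cfg, epochs = 1),
               "minimum")
})
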