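test_that("mse matches direct arithmetic", {
  expect_equal(mse(c(1, 2), c(1, 2)), 0)
  expect_equal(mse(c(0, 0), c(1, -1)), 1)
  expect_equal(mse(c(1, 2, 3), c(2, 2, 2)), 2 / 3)
  expect_error(mse(1:3, 1:2), "mismatch")
  expect_error(mse(numeric(0), numeric(0)), "empty")
})

test_that("distance correlation detects affine dependence and independence", {
  x <- c(1, 2, 3, 4)
  expect_equal(dcor(x, 2 * x + 3), 1, tolerance = 1e-10)
  expect_equal(dcor(x, -x), 1, tolerance = 1e-10)
  expect_identical(dcor(x, rep(1, 4)), 0)
  set.seed(1)
  expect_lt(dcor(rnorm(1000), rnorm(1000)), 0.1)
  expect_error(dcor(1, 1), "at least 2")
})

test_that("dcor is symmetric and shift/scale invariant", {
  set.seed(2)
  x <- rnorm(50)
  y <- x^2 + rnorm(50, sd = 0.2)
  expect_equal(dcor(x, y), dcor(y, x), tolerance = 1e-12)
  expect_equal(dcor(x, y), dcor(3 * x + 1, y), tolerance = 1e-10)
  expect_equal(dcor(x, y), dcor(x, 0.5 * y - 7), tolerance = 1e-10)
  expect_gte(dcor(x, y), 0)
  expect_lte(dcor(x, y), 1)
})

test_that("sparsity counts bit-exact zeros with no epsilon", {
  s <- sparsity(c(0, 0, 0, 1))
  expect_equal(s$zero_fraction, 0.75)
  expect_equal(s$nonzero_fraction, 0.25)
  expect_equal(sparsity(numeric(3))$zero_fraction, 1)
  expect_equal(sparsity(c(1e-300, 0))$zero_fraction, 0.5)
  expect_error(sparsity(numeric(0)), "empty")
  # setting a nonzero weight to zero strictly increases the zero fraction
  w <- c(0.3, 0, -2, 1)
  w2 <- w; w2[1] <- 0
  expect_gt(sparsity(w2)$zero_fraction, sparsity(w)$zero_fraction)
})

test_that("exact Wilcoxon matches enumeration and published tables", {
  expect_equal(wilcoxon_signed_rank_exact(2:11, 1:10)$p_value, 2 / 1024)
  expect_equal(wilcoxon_signed_rank_exact(2:6, 1:5)$p_value, 2 / 32)
  expect_equal(wilcoxon_signed_rank_exact(2:9, 1:8)$p_value, 2 / 256)
  expect_equal(wilcoxon_signed_rank_exact(2, 1)$p_value, 1)
  expect_error(wilcoxon_signed_rank_exact(1:3, 1:3), "no nonzero")
  expect_error(wilcoxon_signed_rank_exact(1:30 + 0.5, 1:30), "25")
})

test_that("exact Wilcoxon agrees with the reference implementation", {
  set.seed(7)
  for (i in 1:10) {
    a <- rnorm(12); b <- rnorm(12)
    ours <- wilcoxon_signed_rank_exact(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  # symmetry under swapping the pair order
  a <- rnorm(9); b <- rnorm(9)
  expect_equal(wilcoxon_signed_rank_exact(a, b)$p_value,
               wilcoxon_signed_rank_exact(b, a)$p_value)
})

test_that("mean (sd) strings render at the requested precision", {
  expect_identical(format_mean_std(c(1, 3)), "2.000 (1.414)")
  expect_identical(format_mean_std(rep(0.5, 10)), "0.500 (0.000)")
  vals <- c(0.131, 0.133, 0.135)
  expect_identical(format_mean_std(vals), "0.133 (0.002)")
  expect_identical(format_mean_std(c(1, 3), decimals = 1), "2.0 (1.4)")
  expect_error(format_mean_std(1), "at least 2")
})
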