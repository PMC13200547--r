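test_that("genotype matrices have the contracted shape and values", {
  cfg <- sim_config(n = 10, p = 7, k_causal = 3, seed = 5)
  G <- simulate_genotypes(cfg)
  expect_identical(dim(G), c(10L, 7L))
  expect_true(all(G %in% 0:2))
  expect_identical(rownames(G)[1], "ind1")
  expect_identical(colnames(G)[7], "snp7")
})

test_that("dosage means track the drawn allele frequencies", {
  cfg <- sim_config(n = 5000, p = 40, maf_range = c(0.5, 0.5), ld_rho = 0,
                    seed = 3)
  G <- simulate_genotypes(cfg)
  expect_equal(mean(colMeans(G)), 1, tolerance = 0.05)
  cfg2 <- sim_config(n = 5000, p = 40, maf_range = c(0.1, 0.1), ld_rho = 0,
                     seed = 3)
  expect_equal(mean(colMeans(simulate_genotypes(cfg2))), 0.2,
               tolerance = 0.05)
})

test_that("latent AR(1) chains induce adjacent-marker correlation", {
  G <- simulate_genotypes(sim_config(n = 5000, p = 80, ld_rho = 0.95,
                                     seed = 4))
  adj <- vapply(seq_len(79), function(j) cor(G[, j], G[, j + 1]), numeric(1))
  expect_gt(mean(adj), 0.6)
  G0 <- simulate_genotypes(sim_config(n = 5000, p = 80, ld_rho = 0,
                                      seed = 4))
  adj0 <- vapply(seq_len(79), function(j) cor(G0[, j], G0[, j + 1]),
                 numeric(1))
  expect_lt(abs(mean(adj0)), 0.05)
})

test_that("identical configurations reproduce identical data", {
  cfg <- sim_config(n = 50, p = 30, k_causal = 5, seed = 77)
  expect_identical(simulate_dataset(cfg), simulate_dataset(cfg))
})

test_that("phenotypes respect the target heritability", {
  r <- vapply(1:3, function(s) {
    d <- simulate_dataset(sim_config(n = 2000, p = 200, k_causal = 30,
                                     h2 = 0.5, seed = s))
    d$truth$realized_h2
  }, numeric(1))
  expect_true(all(abs(r - 0.5) < 0.05))
})

test_that("degenerate heritability settings behave as documented", {
  # noiseless: phenotype is an affine transform of the genetic value
  d <- simulate_dataset(sim_config(n = 200, p = 50, k_causal = 10, h2 = 1,
                                   seed = 9))
  expect_equal(dcor(d$truth$g, d$y), 1, tolerance = 1e-10)
  # pure noise: no genetic contribution, g identically zero
  d0 <- simulate_dataset(sim_config(n = 200, p = 50, k_causal = 0, h2 = 0,
                                    seed = 9))
  expect_identical(d0$truth$g, numeric(200))
  expect_equal(mean(d0$y), 0, tolerance = 1e-12)
  expect_equal(sd(d0$y), 1, tolerance = 1e-12)
  expect_error(simulate_dataset(sim_config(n = 50, p = 20, k_causal = 0,
                                           h2 = 0.5, seed = 1)),
               "undefined")
})

test_that("epistatic interactions enter the genetic value", {
  cfg <- sim_config(n = 500, p = 40, k_causal = 6, n_epistatic_pairs = 3,
                    h2 = 0.8, seed = 12)
  d <- simulate_dataset(cfg)
  expect_identical(nrow(d$truth$epistatic_pairs), 3L)
  # additive-only reconstruction no longer explains g completely
  add <- as.vector(d$G[, d$truth$causal] %*% d$truth$beta)
  expect_gt(stats::var(d$truth$g - add), 0)
})

test_that("invalid simulator settings are rejected", {
  expect_error(sim_config(n = 10, p = 5, k_causal = 2, maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(n = 10, p = 5, k_causal = 2, ld_rho = 1), "ld_rho")
  expect_error(sim_config(n = 10, p = 5, k_causal = 9), "k_causal")
  expect_error(sim_config(n = 10, p = 5, k_causal = 2, h2 = 1.5), "h2")
})
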