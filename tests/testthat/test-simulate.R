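test_that("shifted negative-binomial coverage matches its target moments", {
  cov <- sample_coverage(1e5, mean_cov = 3, var_factor = 3, seed = 5)
  expect_gte(min(cov), 1)
  se_mean <- sd(cov) / sqrt(length(cov))
  expect_lt(abs(mean(cov) - 3), 3 * se_mean)
  se_var <- sd((cov - mean(cov))^2) / sqrt(length(cov))
  expect_lt(abs(var(cov) - 9), 3 * se_var)
})

test_that("coverage dispersion limits behave correctly", {
  # variance just above the shifted-Poisson floor: near-equidispersed draw
  cov <- sample_coverage(5e4, mean_cov = 3, var_factor = 0.7, seed = 6)
  expect_lt(var(cov), 2.6) # target variance 2.1
  expect_gte(min(cov), 1)
  expect_error(sample_coverage(100, 3, 0.6), "infeasible")
})

test_that("moment fit of the shifted negative binomial round-trips", {
  cov <- sample_coverage(1e5, mean_cov = 5, var_factor = 3, seed = 9)
  fit <- fit_shifted_negbin(cov)
  expect_true(fit$feasible)
  expect_equal(fit$mean, 5, tolerance = 0.05)
  expect_equal(fit$variance, 15, tolerance = 0.05)
  # parameterisation: mean 2, variance 9 gives r = 4/7, q = 2/9
  fit2 <- list(mu = 2, v = 9)
  expect_equal(fit$size, (fit$mean - 1)^2 / (fit$variance - (fit$mean - 1)),
    tolerance = 1e-12
  )
  expect_equal(fit$prob, (fit$mean - 1) / fit$variance, tolerance = 1e-12)
  expect_length(fit$theoretical_quantiles, length(cov))
  # honey-bee-like variance/mean ratios are accepted
  expect_true(fit$variance / fit$mean > 2 && fit$variance / fit$mean < 4)

  flat <- fit_shifted_negbin(rep(4, 100))
  expect_false(flat$feasible)
})

test_that("explicit moment matching: mean 3 / variance 9 has r = 4/7, q = 2/9", {
  mu <- 3 - 1
  v <- 3 * 3
  expect_equal(mu^2 / (v - mu), 4 / 7)
  expect_equal(mu / v, 2 / 9)
})

test_that("clustered truth concentrates methylation but preserves the mean", {
  cfg <- sim_config(n_sites = 1e5, pi = 0.005, clustered = TRUE, seed = 3)
  tr <- simulate_truth(cfg)
  expect_equal(mean(tr$in_cluster), 0.1, tolerance = 0.01)
  # in-cluster rate = 10 x pi; out-of-cluster rate exactly 0 at the defaults
  expect_equal(mean(tr$status[tr$in_cluster]), 0.05, tolerance = 0.15)
  expect_false(any(tr$status[!tr$in_cluster]))
  expect_equal(mean(tr$status), 0.005, tolerance = 0.15)

  # homogeneous genome: same expectation, empty cluster mask
  cfg_h <- sim_config(n_sites = 1e5, pi = 0.005, clustered = FALSE, seed = 4)
  tr_h <- simulate_truth(cfg_h)
  expect_false(any(tr_h$in_cluster))
  expect_equal(mean(tr_h$status), 0.005, tolerance = 0.15)
})

test_that("unit cluster intensity reduces to the homogeneous model", {
  cfg <- sim_config(
    n_sites = 5e4, pi = 0.02, clustered = TRUE,
    cluster_intensity = 1, seed = 12
  )
  tr <- simulate_truth(cfg)
  expect_equal(mean(tr$status[tr$in_cluster]), mean(tr$status[!tr$in_cluster]),
    tolerance = 0.15
  )
})

test_that("the alternative out-of-cluster convention keeps rate pi outside", {
  cfg <- sim_config(
    n_sites = 1e5, pi = 0.01, clustered = TRUE,
    preserve_global_mean = FALSE, seed = 8
  )
  tr <- simulate_truth(cfg)
  expect_equal(mean(tr$status[!tr$in_cluster]), 0.01, tolerance = 0.15)
})

test_that("read simulation respects the error-free limit and error rates", {
  status <- c(rep(TRUE, 500), rep(FALSE, 500))
  coverage <- rep(6, 1000)
  k <- simulate_reads(status, coverage, p0 = 0, p1 = 1, seed = 1)
  expect_equal(k, coverage * status)

  set.seed(2)
  k0 <- simulate_reads(rep(FALSE, 2e4), rep(5, 2e4), p0 = 0.002, p1 = 0.7)
  expect_equal(mean(k0) / 5, 0.002, tolerance = 0.15)
  k1 <- simulate_reads(rep(TRUE, 2e4), rep(5, 2e4), p0 = 0.002, p1 = 0.7)
  expect_equal(mean(k1) / 5, 0.7, tolerance = 0.02)
})

test_that("simulated methylomes are reproducible from the seed", {
  cfg <- sim_config(n_sites = 2000, clustered = TRUE, seed = 99)
  expect_identical(simulate_methylome(cfg), simulate_methylome(cfg))
  cfg2 <- sim_config(n_sites = 2000, clustered = TRUE, seed = 100)
  expect_false(identical(simulate_methylome(cfg), simulate_methylome(cfg2)))
})

test_that("simulated tables satisfy the count-table contract", {
  sim <- simulate_methylome(sim_config(n_sites = 1000, spacing = 15, seed = 1))
  expect_equal(sim$pos, 1 + (0:999) * 15)
  expect_true(all(sim$n_meth <= sim$n_total))
  expect_true(all(sim$n_total >= 1))
  # a simulated table feeds straight into both classifiers
  expect_s3_class(classify_binomial(sim, 0.002), "tbl_df")
  expect_s3_class(classify_bayes(sim, 0.002, 0.7), "tbl_df")
})

test_that("invalid simulator configurations are rejected", {
  expect_error(sim_config(pi = 0.2, clustered = TRUE), "exceeds 1")
  expect_error(
    sim_config(pi = 0.005, clustered = TRUE, cluster_fraction = 0.2, cluster_intensity = 6),
    "negative"
  )
  expect_error(sim_config(mean_cov = 3, var_factor = 0.5), "infeasible")
})
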