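test_that("kernel weights follow their closed forms and exclude the focal site", {
  expect_equal(kernel_weight(0, "triangle", 1500), 0)
  expect_equal(kernel_weight(1500, "triangle", 1500), 0)
  expect_equal(kernel_weight(750, "triangle", 1500), 0.5)
  expect_equal(kernel_weight(1500, "laplace", 1500), exp(-1))
  expect_equal(kernel_weight(1500, "gaussian", 1500), exp(-0.5))
  expect_equal(kernel_weight(0, "gaussian", 1500), 0) # K(0) = 0 in all families
  expect_error(kernel_weight(-1), "non-negative")
})

test_that("local level is the read-weighted kernel average of corrected fractions", {
  # focal site plus neighbours at 100 bp (L=2, F=1) and 1000 bp (L=4, F=0.5)
  sites <- meth_sites("c", c(1000, 1100, 2000),
    n_meth = c(0, 2, 2), n_total = c(0, 2, 4)
  )
  pl <- local_levels(sites,
    p0 = 0, p1 = 1, kernel = kernel_spec("triangle", 1500),
    pi_global = 0.5
  )
  w1 <- 1 - 100 / 1500
  w2 <- 1 - 1000 / 1500
  expect_equal(pl[1], (w1 * 2 * 1 + w2 * 4 * 0.5) / (w1 * 2 + w2 * 4))
  expect_equal(pl[1], 0.7916667, tolerance = 1e-6)
})

test_that("neighbourhoods at the non-conversion baseline give level zero", {
  # every neighbour has F = p0 exactly: correction removes the fake signal
  sites <- spaced_sites(n_meth = rep(1, 20), n_total = rep(10, 20), spacing = 100)
  pl <- local_levels(sites, p0 = 0.1, p1 = 0.7, pi_global = 0.3)
  expect_equal(pl, rep(0, 20))
})

test_that("isolated sites fall back to the global level", {
  sites <- meth_sites("c", c(100, 1e6), n_meth = c(1, 1), n_total = c(2, 2))
  pl <- local_levels(sites,
    p0 = 0.002, p1 = 0.7,
    kernel = kernel_spec("triangle", 1500), pi_global = 0.0123
  )
  expect_equal(pl, c(0.0123, 0.0123))
  # windows never span chromosomes
  two <- meth_sites(c("a", "b"), c(100, 200), n_meth = c(2, 0), n_total = c(2, 2))
  pl2 <- local_levels(two, p0 = 0.002, p1 = 0.7, pi_global = 0.05)
  expect_equal(pl2, c(0.05, 0.05))
})

test_that("combined prior mixes endpoints linearly and stays inside (0,1)", {
  expect_equal(combined_prior(0.004, 0.5, w = 0), 0.004)
  expect_equal(combined_prior(0.004, 0.5, w = 1), 0.5)
  expect_equal(combined_prior(0.004, 0.5, w = 0.5), 0.252)
  expect_equal(combined_prior(0, 0, w = 0.5), 1e-6) # floored
  expect_equal(combined_prior(1, 1, w = 0.5), 1 - 1e-6)
  expect_equal(formals(classify_bayes)$w, 0.5) # equal weighting by default
})

test_that("the weight only moves the prior, never the likelihood ratio", {
  cfg <- sim_config(n_sites = 3000, pi = 0.02, clustered = TRUE, seed = 31)
  sim <- simulate_methylome(cfg)
  pi_g <- estimate_global_level(sim, 0.002, 0.7)

  # w = 0 reduces to the pure global-prior Bayes classifier
  c0 <- classify_bayes(sim, 0.002, 0.7, w = 0, pi_global = pi_g)
  direct <- posterior_odds(sim$n_meth, sim$n_total, 0.002, 0.7, pi_g)
  expect_equal(c0$odds, direct)

  # likelihood ratio (odds / prior odds) is invariant in w
  c3 <- classify_bayes(sim, 0.002, 0.7, w = 0.3, pi_global = pi_g)
  c7 <- classify_bayes(sim, 0.002, 0.7, w = 0.7, pi_global = pi_g)
  lr3 <- c3$odds / (c3$prior / (1 - c3$prior))
  lr7 <- c7$odds / (c7$prior / (1 - c7$prior))
  expect_equal(lr3, lr7, tolerance = 1e-9)
})

test_that("triangle, gaussian and laplace kernels give concordant calls", {
  cfg <- sim_config(
    n_sites = 20000, mean_cov = 3, pi = 0.01,
    clustered = TRUE, seed = 5
  )
  sim <- simulate_methylome(cfg)
  calls <- lapply(c("triangle", "gaussian", "laplace"), function(fam) {
    classify_bayes(sim, 0.002, 0.7, kernel = kernel_spec(fam, 1500))$call
  })
  expect_gte(mean(calls[[1]] == calls[[2]]), 0.95)
  expect_gte(mean(calls[[1]] == calls[[3]]), 0.95)
})

test_that("local levels stay in [0, 1] and zero-coverage sites are classified no_data", {
  cfg <- sim_config(n_sites = 5000, mean_cov = 3, pi = 0.01, clustered = TRUE, seed = 13)
  sim <- simulate_methylome(cfg)
  sim$n_total[c(10, 500)] <- 0
  sim$n_meth[c(10, 500)] <- 0
  pl <- local_levels(sim, p0 = 0.002, p1 = 0.7)
  expect_true(all(pl >= 0 & pl <= 1))
  calls <- classify_bayes(sim, 0.002, 0.7)
  expect_equal(nrow(calls), nrow(sim)) # no silent drops
  expect_equal(sum(calls$call == "no_data"), 2)
  # the no-data odds are the bare prior odds
  i <- which(calls$n_total == 0)
  expect_equal(calls$odds[i], calls$prior[i] / (1 - calls$prior[i]))
})

test_that("smoothed tracks reproduce constants, peaks and planted clusters", {
  # constant fractional methylation -> constant track
  const <- spaced_sites(n_meth = rep(2, 50), n_total = rep(4, 50), spacing = 50)
  tr <- smooth_track(const, kernel_spec("triangle", 1500), step = 100)
  expect_true(all(abs(tr$level - 0.5) < 1e-12))

  # single covered site: peak at the site, decaying with the kernel
  single <- meth_sites("c", 5000, n_meth = 4, n_total = 4)
  tr1 <- smooth_track(single, kernel_spec("triangle", 1000), step = 250)
  expect_equal(nrow(tr1), 1) # grid collapses to the lone position
  expect_equal(tr1$level, 1)

  # planted cluster elevates the track inside the cluster region
  cfg <- sim_config(
    n_sites = 10000, mean_cov = 6, pi = 0.02, clustered = TRUE,
    cluster_count = 5, seed = 23
  )
  sim <- simulate_methylome(cfg)
  tr2 <- smooth_track(sim, kernel_spec("triangle", 1500), step = 150)
  in_cl <- vapply(tr2$pos, function(p) {
    any(sim$in_cluster[abs(sim$pos - p) <= 75])
  }, TRUE)
  expect_gt(
    mean(tr2$level[in_cl], na.rm = TRUE),
    5 * mean(tr2$level[!in_cl], na.rm = TRUE)
  )
})
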