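fake_calls <- function(call) tibble::tibble(call = call)

test_that("confusion metrics implement the sparse-methylome definitions", {
  truth <- c(rep(TRUE, 10), rep(FALSE, 40))
  perfect <- fake_calls(ifelse(truth, "methylated", "unmethylated"))
  m <- confusion_metrics(perfect, truth)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$one_minus_specificity_sparse, 0)
  expect_equal(m$accuracy_weighted, 1)

  # 8 of 10 methylated detected -> sensitivity 0.8
  calls <- fake_calls(c(
    rep("methylated", 8), rep("unmethylated", 2),
    rep("unmethylated", 40)
  ))
  expect_equal(confusion_metrics(calls, truth)$sensitivity, 0.8)

  # 2 FP against 50 truly methylated -> sparse ratio 0.04
  truth2 <- c(rep(TRUE, 50), rep(FALSE, 100))
  calls2 <- fake_calls(c(
    rep("methylated", 50),
    rep("methylated", 2), rep("unmethylated", 98)
  ))
  m2 <- confusion_metrics(calls2, truth2)
  expect_equal(m2$one_minus_specificity_sparse, 0.04)
  expect_equal(m2$specificity_standard, 98 / 100)

  # no_data rows are excluded from the confusion counts but reported
  calls3 <- fake_calls(c("methylated", "no_data", "unmethylated"))
  m3 <- confusion_metrics(calls3, c(TRUE, TRUE, FALSE))
  expect_equal(m3$n_no_data, 1)
  expect_equal(m3$tp + m3$fp + m3$tn + m3$fn, 2)
  # counts plus no-data add to the total sites
  expect_equal(m3$tp + m3$fp + m3$tn + m3$fn + m3$n_no_data, m3$n_sites)
})

test_that("AUC follows the midrank formula with correct edge cases", {
  expect_equal(auc_roc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_equal(auc_roc(c(1, 2, 10, 20), c(FALSE, FALSE, TRUE, TRUE)), 1)
  # p-value direction: small means methylated
  expect_equal(auc_roc(c(1e-5, 0.5), c(TRUE, FALSE), direction = "less"), 1)
  expect_error(auc_roc(1:4, rep(TRUE, 4)), "single class")

  set.seed(3)
  scores <- runif(1e4)
  truth <- rep(c(TRUE, FALSE), 5e3)
  expect_equal(auc_roc(scores, truth), 0.5, tolerance = 0.02)
})

test_that("rank AUC equals trapezoidal ROC integration (with ties)", {
  set.seed(4)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    scores <- sample(round(runif(n), 2)) # heavy ties
    truth <- runif(n) < 0.4
    if (length(unique(truth)) < 2) next
    expect_equal(auc_roc(scores, truth), auc_trapezoid(scores, truth),
      tolerance = 1e-12
    )
  }
})

test_that("downsampling to the original coverage reproduces full-data calls", {
  set.seed(5)
  n <- 400
  status <- runif(n) < 0.4
  k <- rbinom(n, 8, ifelse(status, 0.7, 0.002))
  sites <- spaced_sites(n_meth = k, n_total = rep(8, n))
  res <- downsample_experiment(sites,
    p0 = 0.002, p1 = 0.7, high_cov_min = 7,
    target_cov = 8, reps = 1, seed = 1
  )
  # truth set is F < 0.1 / F > 0.3; recompute the reference on that subset
  f <- k / 8
  keep <- f < 0.1 | f > 0.3
  ref_b <- classify_bayes(sites[keep, ], 0.002, 0.7)
  ref_m <- confusion_metrics(ref_b, f[keep] > 0.3)
  got <- res[res$method == "bayes", ]
  expect_equal(got$sensitivity, ref_m$sensitivity)
  expect_equal(got$tp, ref_m$tp)
})

test_that("at one read per site the Bayes caller beats the binomial caller", {
  cfg <- sim_config(
    n_sites = 8000, mean_cov = 9, pi = 0.05, clustered = TRUE,
    seed = 77
  )
  sim <- simulate_methylome(cfg)
  res <- downsample_experiment(sim,
    p0 = 0.002, p1 = 0.7,
    target_cov = 1, reps = 5, seed = 2
  )
  means <- tapply(res$sensitivity, res$method, mean)
  expect_gt(means[["bayes"]], means[["binomial"]])

  # replicate-to-replicate variability shrinks as reps accumulate (s.e. of
  # the mean over 5 reps is smaller than the single-rep spread)
  sens <- res$sensitivity[res$method == "bayes"]
  expect_lt(sd(sens) / sqrt(length(sens)), sd(sens) + 1e-12)
})

test_that("replicate consistency summarises identical and independent calls", {
  cfg <- sim_config(n_sites = 2000, pi = 0.05, clustered = TRUE, seed = 6)
  base <- classify_bayes(simulate_methylome(cfg), 0.002, 0.7)
  same <- list(a = base, b = base, c = base)
  rc <- replicate_consistency(same)
  expect_equal(rc$cv_mcpg_counts, 0)
  expect_equal(rc$pairwise_correlations$correlation, rep(1, 3))

  # independent random calls decorrelate
  set.seed(8)
  rand <- lapply(1:2, function(i) {
    x <- base
    x$call <- sample(c("methylated", "unmethylated"), nrow(x), replace = TRUE)
    x
  })
  rc2 <- replicate_consistency(rand, tile_width = 300)
  expect_lt(abs(rc2$pairwise_correlations$correlation[1]), 0.3)

  # disjoint site universes are rejected
  other <- base
  other$pos <- other$pos + 7
  expect_error(replicate_consistency(list(base, other)), "site universe")
})

test_that("benchmarks are tidy, reproducible, and match the known ordering", {
  grid <- benchmark_grid(
    mean_cov = 3, pi = 0.01, clustered = c(FALSE, TRUE),
    n_sites = 20000
  )
  res <- run_benchmark(grid, reps = 3, seed = 9)
  expect_equal(nrow(res), 2 * 2 * 3) # cells x methods x reps
  expect_true(all(c("method", "rep", "sensitivity", "auc") %in% names(res)))

  # bit-reproducible from the master seed
  expect_identical(res, run_benchmark(grid, reps = 3, seed = 9))

  sm <- summarize_benchmark(res)
  expect_equal(nrow(sm), 4)
  pick <- function(cl, me) sm$sensitivity_mean[sm$clustered == cl & sm$method == me]
  # clustered genomes: the local prior pays off at pi = 0.01
  expect_gt(pick(TRUE, "bayes"), pick(TRUE, "binomial"))
  # the binomial caller ignores position: clustered and homogeneous alike
  expect_equal(pick(TRUE, "binomial"), pick(FALSE, "binomial"), tolerance = 0.1)
  # sparse-ratio error bound holds in the clustered cells
  expect_true(all(
    res$one_minus_specificity_sparse[res$clustered & res$method == "bayes"] < 0.05
  ))
})
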