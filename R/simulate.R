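#' Configuration for the synthetic methylome simulator
#'
#' Collects every knob of the simulator in one validated list.  The
#' defaults reproduce the honey-bee-like regime used to study the
#' classifier: 100,000 CpGs on one synthetic chromosome at a 15 bp spacing
#' (so 200 nearest neighbours span about 3 kb), shifted negative-binomial
#' coverage with variance three times the mean, a sparse global methylation
#' level, non-conversion 0.002 and retention 0.7, and (optionally)
#' methylation concentrated in 1/10 of the genome at 10 times the global
#' intensity.
#'
#' @param n_sites Number of cytosines.
#' @param mean_cov Mean read coverage (typical sparse-methylome datasets
#'   span 3-9).
#' @param var_factor Coverage variance as a multiple of the mean.
#' @param pi Genome-wide probability that a site is methylated.
#' @param clustered If `TRUE`, methylation is concentrated in contiguous
#'   cluster regions; if `FALSE` sites are methylated independently.
#' @param cluster_fraction Fraction of sites inside clusters.
#' @param cluster_intensity Methylation probability inside clusters as a
#'   multiple of `pi`.
#' @param cluster_count Number of equal-length cluster blocks.
#' @param preserve_global_mean If `TRUE` (default) the out-of-cluster rate
#'   is set to `pi * (1 - cluster_fraction * cluster_intensity) /
#'   (1 - cluster_fraction)` so the genome-wide expectation stays `pi`
#'   (zero at the defaults); if `FALSE` the out-of-cluster rate is `pi`
#'   itself.
#' @param p0 Non-conversion rate.
#' @param p1 Probability a methylated C yields a C read.
#' @param eps Sequencing miscall probability folded into the read draw.
#' @param spacing Distance between consecutive sites, bp.
#' @param seed Optional RNG seed making the simulation reproducible.
#' @return A validated list of class `sim_config`.
#' @examples
#' sim_config(n_sites = 1000, mean_cov = 3, clustered = TRUE, seed = 7)
#' @export
sim_config <- function(n_sites = 100000, mean_cov = 5, var_factor = 3,
                       pi = 0.005, clustered = FALSE, cluster_fraction = 0.1,
                       cluster_intensity = 10, cluster_count = 10,
                       preserve_global_mean = TRUE, p0 = 0.002, p1 = 0.7,
                       eps = 0, spacing = 15, seed = NULL) {
  check_number(n_sites, "n_sites", 1, Inf)
  check_number(mean_cov, "mean_cov", 1, Inf, open_lo = TRUE)
  check_number(var_factor, "var_factor", 0, Inf, open_lo = TRUE)
  check_number(pi, "pi", 0, 1, open_lo = TRUE, open_hi = TRUE)
  check_number(cluster_fraction, "cluster_fraction", 0, 1, open_lo = TRUE, open_hi = TRUE)
  check_number(cluster_intensity, "cluster_intensity", 0, Inf, open_lo = TRUE)
  check_number(cluster_count, "cluster_count", 1, Inf)
  check_error_rates(p0, p1)
  check_number(eps, "eps", 0, 0.5, open_hi = TRUE)
  check_number(spacing, "spacing", 1, Inf)
  if (var_factor * mean_cov <= mean_cov - 1) {
    abort("infeasible coverage moments: need var_factor * mean_cov > mean_cov - 1 for the negative-binomial component.")
  }
  if (clustered) {
    if (cluster_intensity * pi > 1) {
      abort("in-cluster methylation probability cluster_intensity * pi exceeds 1.")
    }
    if (preserve_global_mean && cluster_fraction * cluster_intensity > 1) {
      abort("cluster_fraction * cluster_intensity > 1: the out-of-cluster rate would be negative.")
    }
  }
  structure(
    list(
      n_sites = as.integer(n_sites), mean_cov = mean_cov,
      var_factor = var_factor, pi = pi, clustered = isTRUE(clustered),
      cluster_fraction = cluster_fraction,
      cluster_intensity = cluster_intensity,
      cluster_count = as.integer(cluster_count),
      preserve_global_mean = isTRUE(preserve_global_mean),
      p0 = p0, p1 = p1, eps = eps, spacing = spacing, seed = seed
    ),
    class = "sim_config"
  )
}

#' Draw per-site read coverage from a shifted negative binomial
#'
#' `N = 1 + NB(r, q)` with the negative-binomial component matched by
#' moments to mean `mean_cov - 1` and variance `var_factor * mean_cov`
#' (the +1 shift changes the mean, not the variance), so that every site
#' has at least one read while the sample mean and variance converge to
#' `mean_cov` and `var_factor * mean_cov`.
#'
#' @param n Number of sites.
#' @param mean_cov Target mean coverage (> 1).
#' @param var_factor Target variance as a multiple of `mean_cov`.
#' @param seed Optional RNG seed.
#' @return Integer coverages, all at least 1.
#' @examples
#' cov <- sample_coverage(1e4, mean_cov = 3, var_factor = 3, seed = 1)
#' c(mean(cov), var(cov))
#' @export
sample_coverage <- function(n, mean_cov, var_factor = 3, seed = NULL) {
  check_number(mean_cov, "mean_cov", 1, Inf, open_lo = TRUE)
  mu <- mean_cov - 1
  v <- var_factor * mean_cov
  if (v <= mu) {
    abort("infeasible moments: the negative-binomial component needs variance > mean, i.e. var_factor * mean_cov > mean_cov - 1.")
  }
  if (!is.null(seed)) set.seed(seed)
  size <- mu^2 / (v - mu)
  1L + rnbinom(n, size = size, mu = mu)
}

#' Method-of-moments fit of the shifted negative binomial to coverages
#'
#' @param coverages Observed per-site read depths (at least 2 values).
#' @return A list with the sample `mean` and `variance`, the fitted
#'   negative-binomial `size` (r) and success probability `prob` (q) of the
#'   shifted model, a `feasible` flag (the fit requires
#'   `variance > mean - 1`), and `theoretical_quantiles` matched to the
#'   sample for Q-Q plotting (`NULL` when infeasible).
#' @examples
#' fit_shifted_negbin(sample_coverage(1e4, 5, 3, seed = 1))
#' @export
fit_shifted_negbin <- function(coverages) {
  if (length(coverages) < 2 || any(coverages < 1)) {
    abort("`coverages` must hold at least two depths, all >= 1.")
  }
  m <- mean(coverages)
  v <- var(coverages)
  mu <- m - 1
  if (v <= mu || mu <= 0) {
    return(list(
      mean = m, variance = v, size = NA_real_, prob = NA_real_,
      feasible = FALSE, theoretical_quantiles = NULL
    ))
  }
  size <- mu^2 / (v - mu)
  prob <- mu / v # = size / (size + mu)
  list(
    mean = m, variance = v, size = size, prob = prob, feasible = TRUE,
    theoretical_quantiles = 1 + qnbinom(ppoints(length(coverages)), size = size, mu = mu)
  )
}

#' Draw true methylation states (homogeneous or clustered genome)
#'
#' In the homogeneous genome every site is methylated independently with
#' probability `pi`.  In the clustered genome, `cluster_count` contiguous
#' equal-length blocks covering `cluster_fraction` of the sites are placed
#' uniformly without overlap; sites inside clusters are methylated with
#' probability `cluster_intensity * pi` and outside with the rate implied
#' by `preserve_global_mean`, so the genome-wide expectation is `pi` in
#' both modes.
#'
#' @param config A [sim_config()].
#' @return A list with logical vectors `status` (true methylation) and
#'   `in_cluster` (all `FALSE` in homogeneous mode).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_sites
  if (!config$clustered) {
    return(list(
      status = runif(n) < config$pi,
      in_cluster = rep(FALSE, n)
    ))
  }
  n_in <- round(config$cluster_fraction * n)
  block <- max(1L, n_in %/% config$cluster_count)
  cc <- config$cluster_count
  free <- n - cc * block
  if (free < 0) abort("cluster blocks do not fit in the genome.")
  starts <- sort(sample.int(free + 1, cc, replace = TRUE)) + (0:(cc - 1)) * block
  in_cluster <- rep(FALSE, n)
  for (s in starts) in_cluster[(s + 1):(s + block)] <- TRUE

  rate_in <- config$cluster_intensity * config$pi
  frac_in <- mean(in_cluster)
  rate_out <- if (config$preserve_global_mean) {
    max(0, config$pi * (1 - frac_in * config$cluster_intensity) / (1 - frac_in))
  } else {
    config$pi
  }
  status <- runif(n) < ifelse(in_cluster, rate_in, rate_out)
  list(status = status, in_cluster = in_cluster)
}

#' Draw methylated-read counts given true states and coverage
#'
#' `k ~ Binomial(N, p1_eff)` at methylated sites and `Binomial(N, p0_eff)`
#' elsewhere, with the sequencing error `eps` folded into the rates by
#' [effective_error_rates()].
#'
#' @param status Logical vector of true methylation states.
#' @param coverage Integer read depths, same length.
#' @param p0,p1 Conversion error rates.
#' @param eps Sequencing miscall probability.
#' @param seed Optional RNG seed.
#' @return Integer counts of C reads per site.
#' @export
simulate_reads <- function(status, coverage, p0, p1, eps = 0, seed = NULL) {
  if (length(status) != length(coverage)) {
    abort("`status` and `coverage` must have the same length.")
  }
  rates <- effective_error_rates(p0, p1, eps)
  if (!is.null(seed)) set.seed(seed)
  rbinom(
    length(status), coverage,
    ifelse(status, rates$p1_eff, rates$p0_eff)
  )
}

#' Simulate a complete synthetic methylome
#'
#' Composes [simulate_truth()], [sample_coverage()] and [simulate_reads()]
#' into a count table on one synthetic chromosome with uniformly spaced
#' sites, fully reproducible from `config$seed`.  The true state travels
#' with the counts so classifications can be scored against it.
#'
#' @param config A [sim_config()].
#' @return A tibble with the count-table columns (`chrom`, `pos`, `strand`,
#'   `context`, `n_meth`, `n_total`) plus the simulation truth (`status`,
#'   `in_cluster`).
#' @examples
#' sim <- simulate_methylome(sim_config(n_sites = 1000, seed = 1))
#' mean(sim$status)
#' @export
simulate_methylome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_sites
  truth <- local({
    cfg <- config
    cfg$seed <- NULL # RNG already seeded once for the whole composition
    simulate_truth(cfg)
  })
  coverage <- sample_coverage(n, config$mean_cov, config$var_factor)
  n_meth <- simulate_reads(truth$status, coverage, config$p0, config$p1, config$eps)
  tibble(
    chrom = "sim_1",
    pos = 1 + (seq_len(n) - 1) * config$spacing,
    strand = "+", context = "CpG",
    n_meth = as.numeric(n_meth), n_total = as.numeric(coverage),
    status = truth$status, in_cluster = truth$in_cluster
  )
}
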