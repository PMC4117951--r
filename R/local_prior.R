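#' Kernel-weighted local methylation level at every site
#'
#' For each site, averages the error-corrected methylation fractions of its
#' neighbours with kernel weights:
#' `pi_L = sum K(d_k) L_k c_k / sum K(d_k) L_k`, where `L_k` is the
#' neighbour's read count, `c_k = clip((F_k - p0)/(p1 - p0), 0, 1)` its
#' corrected fraction, and the focal site is excluded (`K(0) = 0`).
#' Windows never span chromosome boundaries; zero-coverage neighbours carry
#' no weight.  A site with an empty window falls back to the global level.
#'
#' @inheritParams classify_binomial
#' @param p1 Per-read C probability for methylated sites (`p0 < p1`).
#' @param kernel A [kernel_spec()].
#' @param pi_global Global methylation level used as the fallback; computed
#'   with [estimate_global_level()] when `NULL`.
#' @param weight_by_reads If `TRUE` (default) neighbours are weighted by
#'   their read counts `L_k` inside the kernel average; if `FALSE` every
#'   covered neighbour weighs equally.
#' @return Numeric vector of local levels in `[0, 1]`, aligned to the rows
#'   of `sites` after sorting.
#' @examples
#' sites <- meth_sites("chr1", c(100, 200, 1200),
#'   n_meth = c(2, 0, 2), n_total = c(2, 4, 4)
#' )
#' local_levels(sites, p0 = 0, p1 = 1)
#' @export
local_levels <- function(sites, p0, p1, kernel = kernel_spec(),
                         pi_global = NULL, weight_by_reads = TRUE) {
  sites <- validate_sites(sites)
  check_error_rates(p0, p1)
  if (is.null(pi_global)) pi_global <- estimate_global_level(sites, p0, p1)
  check_number(pi_global, "pi_global", 0, 1)

  f <- frac_meth(sites$n_meth, sites$n_total)
  cval <- clip((f - p0) / (p1 - p0), 0, 1)
  cval[is.na(cval)] <- 0 # annihilated by zero weight anyway
  wts <- if (weight_by_reads) sites$n_total else as.numeric(sites$n_total > 0)

  fam <- kernel_family_code(kernel$family)
  d0 <- if (is.null(kernel$bandwidth)) -1 else kernel$bandwidth
  mode <- if (kernel$mode == "distance") 0L else 1L

  out <- rep(NA_real_, nrow(sites))
  for (ch in split(seq_len(nrow(sites)), sites$chrom)) {
    out[ch] <- local_levels_cpp(
      sites$pos[ch], wts[ch], cval[ch],
      fam, d0, mode, kernel$k, kernel$truncate
    )
  }
  out[is.na(out)] <- pi_global
  out
}

#' Combine global and local methylation levels into a prior
#'
#' `pi_C = (1 - w) * pi_G + w * pi_L`, floored into (0, 1) so that the
#' posterior odds stay finite even in fully unmethylated neighbourhoods.
#' `w = 0.5` treats local and global information equally (the recommended
#' default); `w = 0` reduces the classifier to a pure global-prior Bayes
#' rule.
#'
#' @param pi_global Global methylation level in `[0, 1]`.
#' @param pi_local Local methylation level(s) in `[0, 1]`.
#' @param w Weight on the local level, in `[0, 1]`.
#' @param floor Minimum distance of the prior from 0 and 1.
#' @return The combined prior(s), inside `(0, 1)`.
#' @examples
#' combined_prior(0.004, 0.5, w = 0.5)
#' @export
combined_prior <- function(pi_global, pi_local, w = 0.5, floor = 1e-6) {
  check_number(w, "w", 0, 1)
  check_number(floor, "floor", 0, 0.5, open_lo = TRUE, open_hi = TRUE)
  if (any(pi_global < 0 | pi_global > 1) || any(pi_local < 0 | pi_local > 1)) {
    abort("`pi_global` and `pi_local` must lie in [0, 1].")
  }
  clip((1 - w) * pi_global + w * pi_local, floor, 1 - floor)
}

#' Bayesian methylation calls with a combined global/local prior
#'
#' The full classifier: estimates the global methylation level (unless
#' supplied), computes each site's kernel-weighted local level, mixes the
#' two into a per-site prior, forms posterior odds of methylation against
#' the conversion-error model, and calls sites with odds at or above the
#' cutoff methylated.  Binomial p- and q-values are included alongside for
#' comparison.  Zero-coverage sites are kept with call `"no_data"` so the
#' output aligns row-for-row with the input.
#'
#' @inheritParams local_levels
#' @param w Weight on the local level in the prior (default 0.5).
#' @param cutoff Posterior-odds calling threshold; 19 bounds the per-site
#'   false methylated-call probability at 0.05.
#' @param prior_floor Floor keeping the combined prior inside (0, 1).
#' @return The input table with columns `p_value`, `q_value`, `prior`
#'   (the combined prior used), `odds` and `call` appended.
#' @examples
#' cfg <- sim_config(n_sites = 500, mean_cov = 5, pi = 0.02, clustered = TRUE, seed = 1)
#' calls <- classify_bayes(simulate_methylome(cfg), p0 = 0.002, p1 = 0.7)
#' table(calls$call)
#' @export
classify_bayes <- function(sites, p0, p1, kernel = kernel_spec(), w = 0.5,
                           cutoff = 19, pi_global = NULL, prior_floor = 1e-6,
                           weight_by_reads = TRUE) {
  sites <- validate_sites(sites)
  check_error_rates(p0, p1)
  check_number(cutoff, "cutoff", 0, Inf, open_lo = TRUE)
  if (is.null(pi_global)) pi_global <- estimate_global_level(sites, p0, p1)

  pi_l <- local_levels(sites, p0, p1,
    kernel = kernel, pi_global = pi_global,
    weight_by_reads = weight_by_reads
  )
  prior <- combined_prior(pi_global, pi_l, w = w, floor = prior_floor)
  odds <- posterior_odds(sites$n_meth, sites$n_total, p0, p1, prior)

  covered <- sites$n_total > 0
  p <- rep(NA_real_, nrow(sites))
  q <- rep(NA_real_, nrow(sites))
  if (any(covered)) {
    p[covered] <- binomial_pvalue(sites$n_meth[covered], sites$n_total[covered], p0)
    q[covered] <- bh_qvalues(p[covered])
  }

  mutate(sites,
    p_value = p, q_value = q, prior = prior, odds = odds,
    call = classify_odds(odds, cutoff = cutoff, n_total = sites$n_total)
  )
}

#' Kernel-smoothed methylation track on a regular grid
#'
#' Evaluates the read-count-weighted fractional methylation under the
#' kernel on a regular grid of genomic positions, one track per
#' chromosome.  Unlike the local prior there is no focal site to exclude,
#' so sites at zero distance from a grid point receive full weight.
#'
#' @inheritParams local_levels
#' @param step Grid spacing in bp.
#' @return A tibble with columns `chrom`, `pos`, `level` (`NA` where no
#'   covered site falls inside the kernel support).
#' @examples
#' sites <- meth_sites("chr1", seq(100, 2000, 100),
#'   n_meth = rep(c(4, 0), 10), n_total = 4
#' )
#' smooth_track(sites, step = 500)
#' @export
smooth_track <- function(sites, kernel = kernel_spec(), step = 100) {
  sites <- validate_sites(sites)
  check_number(step, "step", 0, Inf, open_lo = TRUE)
  if (is.null(kernel$bandwidth)) {
    abort("`smooth_track()` needs a kernel with a fixed bandwidth.")
  }
  f <- frac_meth(sites$n_meth, sites$n_total)
  f[is.na(f)] <- 0
  fam <- kernel_family_code(kernel$family)

  out <- lapply(split(seq_len(nrow(sites)), sites$chrom), function(idx) {
    grid <- seq(min(sites$pos[idx]), max(sites$pos[idx]), by = step)
    tibble(
      chrom = sites$chrom[idx[1]], pos = grid,
      level = grid_smooth_cpp(
        grid, sites$pos[idx], sites$n_total[idx], f[idx],
        fam, kernel$bandwidth, kernel$truncate
      )
    )
  })
  bind_rows(out)
}

#' Plot a smoothed methylation track
#'
#' @param track Output of [smooth_track()].
#' @param ... Unused.
#' @return A ggplot object, one panel per chromosome, with the genome-wide
#'   mean level drawn as a reference line.
#' @export
plot_smooth_track <- function(track, ...) {
  ggplot2::ggplot(track, ggplot2::aes(.data$pos, .data$level)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_hline(
      yintercept = mean(track$level, na.rm = TRUE),
      linetype = "dashed", colour = "red"
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "smoothed methylation level")
}
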