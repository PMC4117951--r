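#' Fold sequencing error into the conversion error rates
#'
#' A sequencing miscall flips a C read to T or a T read to C with
#' probability `eps`.  Folding this into the conversion model turns the
#' per-read C probabilities `p0` (non-methylated site, the non-conversion
#' rate) and `p1` (methylated site, one minus the over-conversion rate) into
#' effective rates `p * (1 - eps) + (1 - p) * eps`.  In practice sequencing
#' error is confounded with the conversion errors, so fits on real data
#' return the effective rates directly and `eps` is mainly useful for
#' forward simulation.
#'
#' @param p0 Non-conversion rate: probability that a non-methylated C yields
#'   a C read.
#' @param p1 Probability that a methylated C yields a C read
#'   (1 - over-conversion rate). Must satisfy `p0 < p1`.
#' @param eps Per-read sequencing miscall probability, in `[0, 0.5)`.
#'
#' @return A list with elements `p0_eff` and `p1_eff`.  The ordering
#'   `p0_eff < p1_eff` is preserved for any `eps < 0.5`.
#' @examples
#' effective_error_rates(0.002, 0.7, eps = 0.001)
#' @export
effective_error_rates <- function(p0, p1, eps = 0) {
  check_error_rates(p0, p1)
  check_number(eps, "eps", 0, 0.5, open_hi = TRUE)
  list(
    p0_eff = p0 * (1 - eps) + (1 - p0) * eps,
    p1_eff = p1 * (1 - eps) + (1 - p1) * eps
  )
}

check_error_rates <- function(p0, p1) {
  check_number(p0, "p0", 0, 1)
  check_number(p1, "p1", 0, 1)
  if (p0 >= p1) {
    abort(sprintf(
      "error rates must satisfy p0 < p1 (got p0 = %g, p1 = %g); the model is not identifiable otherwise.",
      p0, p1
    ))
  }
  invisible(NULL)
}

#' Binomial log-likelihood kernel of the read counts at one site
#'
#' Log-probability of observing `k` C reads out of `n` when each read is C
#' independently with probability `rate`, without the binomial coefficient
#' (it is identical under both methylation states and cancels in any odds
#' ratio).  Degenerate rates follow the probability-space convention:
#' incompatible counts give `-Inf`, compatible counts give 0.
#'
#' @param k Number of C reads (vectorised).
#' @param n Total reads (vectorised).
#' @param rate Per-read probability of a C read.
#' @return `k * log(rate) + (n - k) * log(1 - rate)`.
#' @examples
#' site_log_likelihood(3, 10, 0.002)
#' @export
site_log_likelihood <- function(k, n, rate) {
  r <- vctrs_recycle(k = k, n = n, rate = rate)
  if (any(r$k < 0 | r$k > r$n)) abort("`k` must satisfy 0 <= k <= n.")
  if (any(r$rate < 0 | r$rate > 1)) abort("`rate` must be in [0, 1].")
  t1 <- ifelse(r$k == 0, 0, r$k * log(r$rate))
  t2 <- ifelse(r$n - r$k == 0, 0, (r$n - r$k) * log1p(-r$rate))
  t1 + t2
}

# minimal common-length recycling for a few numeric vectors
vctrs_recycle <- function(...) {
  xs <- list(...)
  len <- max(vapply(xs, length, 1L))
  lapply(xs, rep_len, length.out = len)
}

#' Posterior odds of methylation at a site
#'
#' Combines a prior probability of methylation with the likelihood ratio of
#' the observed counts under the methylated (per-read C probability `p1`)
#' versus non-methylated (`p0`) states:
#' `odds = prior/(1-prior) * p1^k (1-p1)^(n-k) / (p0^k (1-p0)^(n-k))`.
#' Computed in log space; a site with no reads returns the bare prior odds.
#'
#' @inheritParams site_log_likelihood
#' @param p0,p1 Effective per-read C probabilities for the non-methylated
#'   and methylated states (`p0 < p1`).
#' @param prior Prior probability of methylation, strictly inside (0, 1).
#'   May be a vector (e.g. a per-site combined prior).
#' @return Posterior odds `P(methylated | reads) / P(non-methylated | reads)`.
#' @examples
#' posterior_odds(1, 1, p0 = 0.002, p1 = 0.7, prior = 0.01)
#' @export
posterior_odds <- function(k, n, p0, p1, prior) {
  check_error_rates(p0, p1)
  if (any(!is.finite(prior) | prior <= 0 | prior >= 1)) {
    abort("`prior` must lie strictly inside (0, 1); a degenerate prior makes the odds trivial.")
  }
  log_odds <- log(prior) - log1p(-prior) +
    site_log_likelihood(k, n, p1) - site_log_likelihood(k, n, p0)
  exp(log_odds)
}

#' Classify sites from posterior odds
#'
#' @param odds Posterior odds of methylation.
#' @param cutoff Calling threshold; odds greater than or equal to the cutoff
#'   are called methylated.  The default 19 corresponds to a posterior
#'   methylation probability of at least 0.95, i.e. a per-site probability
#'   of a false methylated call below 0.05.
#' @param n_total Optional total read counts; sites with `n_total == 0` are
#'   reported as `"no_data"` rather than called.
#' @return Character vector with values `"methylated"`, `"unmethylated"`,
#'   `"no_data"`.
#' @examples
#' classify_odds(c(19, 18.99), cutoff = 19)
#' @export
classify_odds <- function(odds, cutoff = 19, n_total = NULL) {
  check_number(cutoff, "cutoff", 0, Inf, open_lo = TRUE)
  if (any(odds < 0, na.rm = TRUE)) abort("`odds` must be non-negative.")
  out <- ifelse(odds >= cutoff, "methylated", "unmethylated")
  if (!is.null(n_total)) out[n_total == 0] <- "no_data"
  out
}

#' Smallest odds cutoff bounding the false-methylated probability
#'
#' A cutoff `c` on posterior odds guarantees that a called site is
#' non-methylated with probability at most `1/(1+c)`; the smallest cutoff
#' achieving a bound `alpha` is therefore `(1 - alpha)/alpha` (19 at the
#' default `alpha = 0.05`).
#'
#' @param alpha Bound on the per-site probability of a false methylated
#'   call.
#' @return The odds cutoff.
#' @examples
#' odds_cutoff(0.05)
#' @export
odds_cutoff <- function(alpha = 0.05) {
  check_number(alpha, "alpha", 0, 1, open_lo = TRUE, open_hi = TRUE)
  (1 - alpha) / alpha
}
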