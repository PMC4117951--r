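#' Estimate conversion error rates by EM on a binomial mixture
#'
#' Fits the two-component binomial mixture that underlies the classifier:
#' each covered site is methylated with probability `pi`, and its C-read
#' count is `Binomial(n, p1)` when methylated and `Binomial(n, p0)` when
#' not.  The E-step computes the posterior responsibility of the methylated
#' component per site; the M-step updates `pi` as the mean responsibility
#' and `p0`, `p1` as responsibility-weighted C-read fractions.  Iteration
#' stops when the observed-data log-likelihood changes by less than `tol`.
#' The component labels are swapped on exit if needed so that
#' `p0_hat < p1_hat`.
#'
#' Sites with no reads are excluded from the fit.  If the data contain no C
#' reads at all the mixture is degenerate; the fit is returned with
#' `converged = FALSE` and `p1_hat` at its initial value.
#'
#' @param sites Per-site count table (see [meth_sites()]).
#' @param init Optional named list with starting values `p0`, `p1`, `pi`
#'   (defaults: 0.005, 0.5, and the raw genome-wide C-read fraction).
#' @param tol Absolute convergence tolerance on the log-likelihood.
#' @param max_iter Maximum number of EM iterations.
#' @return An object of class `meth_em`: a list with `p0_hat`, `p1_hat`,
#'   `pi_hat`, `responsibilities` (aligned to the input rows, `NA` at
#'   uncovered sites), `loglik_trace`, `n_iter`, `converged`,
#'   `n_sites_used`.
#' @seealso [estimate_global_level()] for the moment-based estimator of the
#'   global level given known error rates; [tidy.meth_em()] and
#'   [glance.meth_em()].
#' @examples
#' cfg <- sim_config(n_sites = 2000, mean_cov = 5, pi = 0.02, seed = 1)
#' fit <- fit_error_em(simulate_methylome(cfg))
#' glance(fit)
#' @export
fit_error_em <- function(sites, init = NULL, tol = 1e-8, max_iter = 500L) {
  sites <- validate_sites(sites)
  covered <- sites$n_total > 0
  if (!any(covered)) abort("EM needs at least one covered site.")
  k <- sites$n_meth[covered]
  n <- sites$n_total[covered]
  f_tot <- sum(k) / sum(n)

  init <- modifyList(
    list(p0 = 0.005, p1 = 0.5, pi = clip(f_tot, 1e-6, 1 - 1e-6)),
    init %||% list()
  )
  check_error_rates(init$p0, init$p1)
  check_number(init$pi, "init$pi", 0, 1, open_lo = TRUE, open_hi = TRUE)

  resp_all <- rep(NA_real_, nrow(sites))
  if (sum(k) == 0) {
    warn("all C-read counts are zero: the methylated component is unidentifiable.")
    resp_all[covered] <- 0
    return(new_meth_em(
      p0_hat = 0, p1_hat = init$p1, pi_hat = 1e-6,
      responsibilities = resp_all, loglik_trace = numeric(0),
      n_iter = 0L, converged = FALSE, n_sites_used = sum(covered),
      init = init, tol = tol
    ))
  }

  # collapse to unique (k, n) pairs: the likelihood only depends on counts
  agg <- count(tibble(k = k, n = n), .data$k, .data$n, name = "wt")
  eps_p <- 1e-12
  p0 <- init$p0
  p1 <- init$p1
  pi1 <- init$pi
  ll_trace <- numeric(0)
  converged <- FALSE
  ll_prev <- -Inf

  mix_ll <- function(p0, p1, pi1) {
    la <- log(pi1) + dbinom(agg$k, agg$n, p1, log = TRUE)
    lb <- log1p(-pi1) + dbinom(agg$k, agg$n, p0, log = TRUE)
    mx <- pmax(la, lb)
    ll_i <- mx + log(exp(la - mx) + exp(lb - mx))
    list(ll = sum(agg$wt * ll_i), gamma = exp(la - ll_i))
  }

  iter <- 0L
  for (iter in seq_len(max_iter)) {
    e <- mix_ll(p0, p1, pi1)
    if (!is.finite(e$ll)) abort("non-finite log-likelihood in EM.")
    ll_trace <- c(ll_trace, e$ll)
    if (iter > 1L && abs(e$ll - ll_prev) < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- e$ll
    g <- e$gamma
    wt <- agg$wt
    pi1 <- clip(sum(wt * g) / sum(wt), eps_p, 1 - eps_p)
    p1 <- clip(sum(wt * g * agg$k) / sum(wt * g * agg$n), eps_p, 1 - eps_p)
    p0 <- clip(
      sum(wt * (1 - g) * agg$k) / sum(wt * (1 - g) * agg$n),
      eps_p, 1 - eps_p
    )
  }

  if (p0 > p1) { # label swap to enforce identifiability
    tmp <- p0
    p0 <- p1
    p1 <- tmp
    pi1 <- 1 - pi1
  }

  e <- mix_ll(p0, p1, pi1)
  g_site <- {
    la <- log(pi1) + dbinom(k, n, p1, log = TRUE)
    lb <- log1p(-pi1) + dbinom(k, n, p0, log = TRUE)
    mx <- pmax(la, lb)
    exp(la - (mx + log(exp(la - mx) + exp(lb - mx))))
  }
  resp_all[covered] <- g_site

  new_meth_em(
    p0_hat = p0, p1_hat = p1, pi_hat = pi1,
    responsibilities = resp_all, loglik_trace = ll_trace,
    n_iter = iter, converged = converged, n_sites_used = sum(covered),
    init = init, tol = tol
  )
}

new_meth_em <- function(...) {
  structure(list(...), class = "meth_em")
}

#' @export
print.meth_em <- function(x, ...) {
  cat("Binomial-mixture EM fit of bisulfite error rates\n")
  cat(sprintf(
    "  p0 (non-conversion)      : %.6g\n  p1 (1 - over-conversion) : %.6g\n  pi (global methylation)  : %.6g\n",
    x$p0_hat, x$p1_hat, x$pi_hat
  ))
  cat(sprintf(
    "  %d sites, %d iterations, converged: %s\n",
    x$n_sites_used, x$n_iter, x$converged
  ))
  invisible(x)
}

#' Tidy an EM error-rate fit
#'
#' @param x A `meth_em` object from [fit_error_em()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.meth_em <- function(x, ...) {
  tibble(
    term = c("p0", "p1", "pi"),
    estimate = c(x$p0_hat, x$p1_hat, x$pi_hat)
  )
}

#' One-row summary of an EM error-rate fit
#'
#' @inheritParams tidy.meth_em
#' @return A one-row tibble with the estimates, final log-likelihood,
#'   iteration count and convergence flag.
#' @export
glance.meth_em <- function(x, ...) {
  tibble(
    p0_hat = x$p0_hat, p1_hat = x$p1_hat, pi_hat = x$pi_hat,
    loglik = if (length(x$loglik_trace)) tail(x$loglik_trace, 1) else NA_real_,
    n_iter = x$n_iter, converged = x$converged, n_sites = x$n_sites_used
  )
}

#' Plot the EM log-likelihood trace
#'
#' @param object A `meth_em` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meth_em <- function(object, ...) {
  df <- tibble(
    iteration = seq_along(object$loglik_trace),
    loglik = object$loglik_trace
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = "EM iteration", y = "log-likelihood",
      title = "Binomial-mixture EM convergence"
    )
}

#' Moment-based global methylation level corrected for conversion errors
#'
#' The expected genome-wide C-read fraction is
#' `E[F] = pi * p1 + (1 - pi) * p0`; inverting gives
#' `pi = (F_tot - p0) / (p1 - p0)`, clipped into `(floor, 1 - floor)`.
#' This extends the raw fractional methylation level: with `p1 < 1` the
#' corrected level sits below the raw fraction for sparse methylomes, and a
#' positive `p0` pulls it down further.
#'
#' @inheritParams classify_binomial
#' @param p1 Probability a methylated C yields a C read (`p0 < p1`).
#' @param floor Clipping floor keeping the estimate inside (0, 1).
#' @return The estimated global methylation level, a single number.
#' @examples
#' sites <- meth_sites("chr1", 1:50 * 10, n_meth = rbinom(50, 5, 0.005), n_total = 5)
#' estimate_global_level(sites, p0 = 0.002, p1 = 0.7)
#' @export
estimate_global_level <- function(sites, p0, p1, floor = 1e-6) {
  sites <- validate_sites(sites)
  check_error_rates(p0, p1)
  total <- sum(sites$n_total)
  if (total <= 0) abort("cannot estimate a methylation level without reads.")
  f_tot <- sum(sites$n_meth) / total
  clip((f_tot - p0) / (p1 - p0), floor, 1 - floor)
}
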