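#' Upper-tail binomial p-value for the "site is unmethylated" null
#'
#' The baseline caller tests, at each covered site, the null hypothesis
#' that the site is non-methylated and its C reads arise solely from
#' non-conversion: `p = P(X >= k)` for `X ~ Binomial(n, p0)`.
#'
#' @param k Number of C reads (vectorised).
#' @param n Total reads; must be at least 1 (a site with no reads has no
#'   test).
#' @param p0 Non-conversion rate used as the null success rate.
#' @return Upper-tail p-values including `k` itself.
#' @examples
#' binomial_pvalue(1, 3, p0 = 0.002)
#' @export
binomial_pvalue <- function(k, n, p0) {
  check_number(p0, "p0", 0, 1, open_lo = TRUE, open_hi = TRUE)
  r <- vctrs_recycle(k = k, n = n)
  if (any(r$n < 1)) {
    abort("`n` must be >= 1: the binomial test is undefined at zero coverage (this is not p = 1).")
  }
  if (any(r$k < 0 | r$k > r$n)) abort("`k` must satisfy 0 <= k <= n.")
  pbinom(r$k - 1, r$n, p0, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up false discovery rate adjustment
#' (`q_(i) = min_{j >= i} p_(j) * N / j`, capped at 1), as used to correct
#' the per-site binomial p-values for the genome-wide number of tests.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @return q-values in the original order; empty input gives empty output.
#' @examples
#' bh_qvalues(c(0.001, 0.01, 0.02, 0.9))
#' @export
bh_qvalues <- function(p_values) {
  if (length(p_values) == 0) {
    return(numeric(0))
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("`p_values` must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Call methylation with the binomial test and FDR correction
#'
#' The widely used baseline: a one-sided binomial test of "unmethylated"
#' at every covered site, Benjamini-Hochberg correction over all covered
#' sites of the table, and a call of methylated where `q < alpha`.  Sites
#' with no reads are carried through with call `"no_data"` and are not part
#' of the FDR family.
#'
#' @param sites Per-site count table (see [meth_sites()]).
#' @param p0 Non-conversion rate (from a spike-in / unmethylated-fraction
#'   estimate or from [fit_error_em()]).
#' @param alpha q-value threshold for calling a site methylated.
#' @return The input table with columns `p_value`, `q_value`, `prior`,
#'   `odds` (both `NA` for this method) and `call` appended.
#' @examples
#' sites <- meth_sites("chr1", c(10, 20), n_meth = c(5, 0), n_total = c(5, 5))
#' classify_binomial(sites, p0 = 0.002)
#' @export
classify_binomial <- function(sites, p0, alpha = 0.05) {
  sites <- validate_sites(sites)
  check_number(alpha, "alpha", 0, 1, open_lo = TRUE, open_hi = TRUE)
  covered <- sites$n_total > 0
  p <- rep(NA_real_, nrow(sites))
  if (any(covered)) {
    p[covered] <- binomial_pvalue(sites$n_meth[covered], sites$n_total[covered], p0)
  }
  q <- rep(NA_real_, nrow(sites))
  q[covered] <- bh_qvalues(p[covered])
  out <- mutate(sites,
    p_value = p, q_value = q,
    prior = NA_real_, odds = NA_real_,
    call = dplyr::case_when(
      .data$n_total == 0 ~ "no_data",
      q < alpha ~ "methylated",
      TRUE ~ "unmethylated"
    )
  )
  out
}

#' Smallest genome methylation level at which a site can be called
#'
#' Under Benjamini-Hochberg at level `alpha`, a site with p-value `p` is
#' callable only when its p-value percentile among all tests is at least
#' `p / alpha`.  Because p-value percentiles track the genome-wide
#' methylation level in a sparsely methylated genome, `p / alpha`
#' approximates the smallest global methylation level at which the binomial
#' method can ever call the site.  Values above 1 mean the site can never
#' be called.
#'
#' @inheritParams binomial_pvalue
#' @param alpha FDR threshold.
#' @return `binomial_pvalue(k, n, p0) / alpha`, as a fraction.
#' @examples
#' min_calling_percentile(1, 1, p0 = 0.002) # 0.04: needs >= 4% methylation
#' min_calling_percentile(1, 3, p0 = 0.002) # ~0.12
#' @export
min_calling_percentile <- function(k, n, p0, alpha = 0.05) {
  check_number(alpha, "alpha", 0, 1, open_lo = TRUE, open_hi = TRUE)
  binomial_pvalue(k, n, p0) / alpha
}
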