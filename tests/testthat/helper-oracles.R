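# Independent oracles used by the unit and acceptance tests.  These stay
# deliberately naive (sorting, enumeration, trapezoids) so they cannot share
# a failure mode with the package's implementations.

# Benjamini-Hochberg by explicit sort / scale / cumulative-min from the
# largest rank.
bh_brute_force <- function(p) {
  n <- length(p)
  if (n == 0) {
    return(numeric(0))
  }
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Posterior methylation probability by direct enumeration of Bayes' rule on
# the two-state model, using dbinom for the full binomial likelihood.
bayes_posterior_enum <- function(k, n, p0, p1, prior) {
  a <- prior * dbinom(k, n, p1)
  b <- (1 - prior) * dbinom(k, n, p0)
  a / (a + b)
}

# ROC area by explicit threshold sweep and trapezoidal integration; with
# tied scores this equals the midrank Mann-Whitney statistic.
auc_trapezoid <- function(scores, truth) {
  truth <- as.logical(truth)
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(scores[truth] >= t), 1)
  fpr <- vapply(th, function(t) mean(scores[!truth] >= t), 1)
  fpr <- c(0, fpr, 1)
  tpr <- c(0, tpr, 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Uniformly spaced single-chromosome site table, handy for hand-built cases.
spaced_sites <- function(n_meth, n_total, spacing = 15, chrom = "c1") {
  meth_sites(chrom, 1 + (seq_along(n_total) - 1) * spacing,
    n_meth = n_meth, n_total = n_total, strand = "+"
  )
}
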