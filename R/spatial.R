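#' Spatial autocorrelation of methylation levels versus distance
#'
#' For every distance bin, the Pearson correlation of fractional
#' methylation over all same-chromosome pairs of sites whose separation
#' falls in the bin.  Only sites with coverage at least `min_coverage` are
#' paired, so that the fractions entering the correlation are reasonably
#' stable.  Bins with fewer than two pairs (or degenerate variance) are
#' reported as missing, not zero.
#'
#' @inheritParams classify_binomial
#' @param max_dist Largest pair separation considered, bp.
#' @param bin_width Width of the distance bins, bp.
#' @param min_coverage Minimum coverage for a site to enter a pair.
#' @return A tibble of class `meth_corr_curve` with columns `bin_low`,
#'   `bin_high`, `bin_mid`, `correlation`, `n_pairs`.
#' @examples
#' cfg <- sim_config(
#'   n_sites = 3000, mean_cov = 8, pi = 0.02,
#'   clustered = TRUE, seed = 1
#' )
#' curve <- correlation_curve(simulate_methylome(cfg))
#' select_bandwidth(curve)
#' @export
correlation_curve <- function(sites, max_dist = 5000, bin_width = 50,
                              min_coverage = 4) {
  sites <- validate_sites(sites)
  check_number(max_dist, "max_dist", 0, Inf, open_lo = TRUE)
  check_number(bin_width, "bin_width", 0, Inf, open_lo = TRUE)
  check_number(min_coverage, "min_coverage", 0, Inf)

  keep <- sites$n_total >= max(min_coverage, 1)
  nb <- ceiling(max_dist / bin_width)
  # per-bin sufficient statistics for a Pearson correlation over pairs
  stats <- matrix(0, nrow = nb, ncol = 6,
    dimnames = list(NULL, c("n", "sx", "sy", "sxx", "syy", "sxy"))
  )

  for (idx in split(which(keep), sites$chrom[keep])) {
    pos <- sites$pos[idx]
    f <- sites$n_meth[idx] / sites$n_total[idx]
    np <- length(pos)
    if (np < 2) next
    lag <- 1L
    while (lag < np) {
      d <- pos[(lag + 1):np] - pos[1:(np - lag)]
      if (min(d) > max_dist) break # separations only grow with the lag
      sel <- which(d <= max_dist & d > 0)
      if (length(sel) > 0) {
        b <- pmin(ceiling(d[sel] / bin_width), nb)
        x <- f[sel]
        y <- f[sel + lag]
        add <- rowsum(cbind(1, x, y, x * x, y * y, x * y), b)
        rows <- as.integer(rownames(add))
        stats[rows, ] <- stats[rows, , drop = FALSE] + add
      }
      lag <- lag + 1L
    }
  }

  n <- stats[, "n"]
  cov_xy <- stats[, "sxy"] - stats[, "sx"] * stats[, "sy"] / n
  var_x <- stats[, "sxx"] - stats[, "sx"]^2 / n
  var_y <- stats[, "syy"] - stats[, "sy"]^2 / n
  r <- ifelse(n >= 2 & var_x > 0 & var_y > 0,
    cov_xy / sqrt(var_x * var_y), NA_real_
  )

  out <- tibble(
    bin_low = (seq_len(nb) - 1) * bin_width,
    bin_high = pmin(seq_len(nb) * bin_width, max_dist),
    bin_mid = ((seq_len(nb) - 1) * bin_width + pmin(seq_len(nb) * bin_width, max_dist)) / 2,
    correlation = as.numeric(r),
    n_pairs = as.integer(n)
  )
  structure(out,
    class = c("meth_corr_curve", class(out)),
    max_dist = max_dist, bin_width = bin_width, min_coverage = min_coverage
  )
}

#' Choose the kernel bandwidth from a correlation curve
#'
#' Returns the midpoint of the first distance bin at which the spatial
#' correlation drops below `threshold` and stays below it in the following
#' bin (a single noisy dip does not count).  If the correlation never
#' drops below the threshold the maximum distance of the curve is returned
#' with a warning.
#'
#' @param curve A [correlation_curve()] result.
#' @param threshold Correlation level defining the bandwidth (default 0.2,
#'   which lands near 1.5 kb on honey-bee-like methylomes).
#' @return Bandwidth in bp, with attribute `threshold_crossed` saying
#'   whether the threshold was actually reached.
#' @export
select_bandwidth <- function(curve, threshold = 0.2) {
  check_number(threshold, "threshold", -1, 1)
  ok <- !is.na(curve$correlation)
  if (!any(ok)) abort("the correlation curve has no defined bins.")
  mids <- curve$bin_mid[ok]
  corr <- curve$correlation[ok]
  m <- length(corr)
  below <- corr < threshold
  sustained <- below & c(below[-1], TRUE) # below here and in the next bin
  hit <- which(sustained)
  if (length(hit) == 0) {
    warn(sprintf(
      "correlation never drops below %g up to %g bp; returning max_dist.",
      threshold, attr(curve, "max_dist")
    ))
    return(structure(attr(curve, "max_dist"), threshold_crossed = FALSE))
  }
  structure(mids[hit[1]], threshold_crossed = TRUE)
}

#' Plot a spatial correlation curve
#'
#' @param object A `meth_corr_curve`.
#' @param threshold Optional horizontal reference line (the bandwidth
#'   selection threshold).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meth_corr_curve <- function(object, threshold = 0.2, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$bin_mid, .data$correlation)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 0.7, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(
      x = "distance between CpG pairs (bp)",
      y = "Pearson correlation of methylation level"
    )
}

#' Write a correlation curve as TSV
#'
#' @param curve A [correlation_curve()] result.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_correlation_curve <- function(curve, path) {
  readr::write_tsv(
    as_tibble(curve)[, c("bin_mid", "correlation", "n_pairs")], path
  )
  invisible(path)
}
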