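#' Confusion-matrix metrics for methylation calls
#'
#' Scores a call table against the true methylation states.  Sites with
#' call `"no_data"` are excluded from the confusion counts but reported.
#' Alongside the standard sensitivity and specificity, the nonstandard
#' error ratio used for sparse methylomes is reported separately:
#' `one_minus_specificity_sparse`, the number of falsely methylated calls
#' divided by the number of truly methylated (covered) sites.  That
#' normalisation keeps the error measure on the same scale as sensitivity
#' when the two classes are wildly unbalanced.
#'
#' @param calls A call table from [classify_bayes()] or
#'   [classify_binomial()] (needs a `call` column).
#' @param truth Logical vector of true states, index-aligned with `calls`
#'   (or a data frame with a `status` column).
#' @return A one-row tibble with counts (`tp`, `fp`, `tn`, `fn`,
#'   `n_no_data`), `sensitivity`, `specificity_standard`,
#'   `one_minus_specificity_sparse` and `accuracy_weighted`
#'   (`P(m) * sens + P(nm) * spec` over covered sites).
#' @examples
#' cfg <- sim_config(n_sites = 2000, pi = 0.02, clustered = TRUE, seed = 2)
#' sim <- simulate_methylome(cfg)
#' confusion_metrics(classify_binomial(sim, p0 = 0.002), sim$status)
#' @export
confusion_metrics <- function(calls, truth) {
  if (is.data.frame(truth)) truth <- truth$status
  if (length(truth) != nrow(calls)) {
    abort("`truth` must align with the rows of `calls`.")
  }
  scored <- calls$call != "no_data"
  called <- calls$call[scored] == "methylated"
  tr <- truth[scored]

  tp <- sum(called & tr)
  fp <- sum(called & !tr)
  fn <- sum(!called & tr)
  tn <- sum(!called & !tr)
  n_meth <- tp + fn
  n_unmeth <- fp + tn

  sens <- if (n_meth > 0) tp / n_meth else NA_real_
  spec <- if (n_unmeth > 0) tn / n_unmeth else NA_real_
  tibble(
    n_sites = nrow(calls), tp = tp, fp = fp, tn = tn, fn = fn,
    n_no_data = sum(!scored),
    sensitivity = sens,
    specificity_standard = spec,
    one_minus_specificity_sparse = if (n_meth > 0) fp / n_meth else NA_real_,
    accuracy_weighted = if (n_meth + n_unmeth > 0) {
      (n_meth * ifelse(is.na(sens), 0, sens) +
        n_unmeth * ifelse(is.na(spec), 0, spec)) / (n_meth + n_unmeth)
    } else {
      NA_real_
    }
  )
}

#' Area under the ROC curve by the rank (Mann-Whitney) formula
#'
#' @param scores Per-site scores: posterior odds (higher means methylated)
#'   or p-values (lower means methylated, set `direction = "less"`).
#' @param truth Logical vector of true states.
#' @param direction `"greater"` if large scores indicate methylation,
#'   `"less"` if small scores do.
#' @return The AUC, with midrank handling of ties (identical scores for
#'   all sites give 0.5).
#' @examples
#' auc_roc(c(3, 9, 1, 7), c(FALSE, TRUE, FALSE, TRUE))
#' @export
auc_roc <- function(scores, truth, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (is.data.frame(truth)) truth <- truth$status
  keep <- !is.na(scores) & !is.na(truth)
  scores <- scores[keep]
  truth <- as.logical(truth[keep])
  n1 <- sum(truth)
  n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) {
    abort("AUC is undefined when the truth has a single class.")
  }
  if (direction == "less") scores <- -scores
  r <- rank(scores, ties.method = "average")
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Coverage-downsampling comparison on coverage-rich sites
#'
#' Reproduces the confirmation experiment for real data: coverage-rich
#' sites (depth at least `high_cov_min`) define a truth set — fractional
#' methylation below `unmeth_max_frac` is taken as truly unmethylated,
#' above `meth_min_frac` as truly methylated, intermediate sites are
#' excluded.  Each site's reads are then subsampled without replacement
#' (hypergeometrically) to `target_cov` reads, both callers are rerun on
#' the reduced data, and the confusion metrics are recorded per replicate.
#'
#' @inheritParams classify_bayes
#' @param high_cov_min Minimum depth for the truth set.
#' @param unmeth_max_frac,meth_min_frac Fraction cutoffs defining the
#'   truth classes.
#' @param target_cov Reduced coverages to test (e.g. `1:3`).
#' @param reps Number of subsampling replicates.
#' @param seed Optional master seed.
#' @param alpha FDR threshold for the binomial caller.
#' @return A tidy tibble with one row per (method, target_cov, rep):
#'   confusion metrics plus `auc`.
#' @examples
#' cfg <- sim_config(n_sites = 2000, mean_cov = 9, pi = 0.05, clustered = TRUE, seed = 3)
#' res <- downsample_experiment(simulate_methylome(cfg),
#'   p0 = 0.002, p1 = 0.7,
#'   target_cov = 1, reps = 2, seed = 1
#' )
#' @export
downsample_experiment <- function(sites, p0, p1, high_cov_min = 7,
                                  unmeth_max_frac = 0.1, meth_min_frac = 0.3,
                                  target_cov = 1:3, reps = 10, seed = NULL,
                                  kernel = kernel_spec(), w = 0.5,
                                  cutoff = 19, alpha = 0.05) {
  sites <- validate_sites(sites)
  rich <- filter(sites, .data$n_total >= high_cov_min)
  f <- rich$n_meth / rich$n_total
  rich <- mutate(rich, status = f > meth_min_frac)[f < unmeth_max_frac | f > meth_min_frac, ]
  if (nrow(rich) < 2 || length(unique(rich$status)) < 2) {
    abort("not enough coverage-rich sites in both truth classes.")
  }
  if (!is.null(seed)) set.seed(seed)

  grid <- tidyr::expand_grid(rep = seq_len(reps), target_cov = target_cov)
  purrr::pmap(grid, function(rep, target_cov) {
    usable <- rich[rich$n_total >= target_cov, ]
    sub <- mutate(usable,
      n_meth = as.numeric(rhyper(
        n(),
        m = .data$n_meth, n = .data$n_total - .data$n_meth, k = target_cov
      )),
      n_total = as.numeric(target_cov)
    )
    bayes <- classify_bayes(sub, p0, p1,
      kernel = kernel, w = w, cutoff = cutoff
    )
    binom <- classify_binomial(sub, p0, alpha = alpha)
    bind_rows(
      mutate(confusion_metrics(bayes, sub$status),
        method = "bayes",
        auc = auc_roc(bayes$odds, sub$status, "greater")
      ),
      mutate(confusion_metrics(binom, sub$status),
        method = "binomial",
        auc = auc_roc(binom$p_value, sub$status, "less")
      )
    ) |>
      mutate(target_cov = target_cov, rep = rep, .before = 1)
  }) |>
    bind_rows()
}

#' Consistency of calls across biological replicates
#'
#' Two summaries of how reproducible a caller is across replicate samples
#' sharing a site universe: the coefficient of variation of the number of
#' methylated calls per sample, and pairwise Pearson correlations of
#' per-feature methylation levels (fraction of called sites that are
#' methylated within each feature).  Features are user-supplied BED-style
#' intervals or, by default, fixed-width genomic tiles.
#'
#' @param call_tables A named list of call tables over the same sites.
#' @param features Optional tibble of intervals (`chrom`, `start`, `end`,
#'   0-based half-open), e.g. from [read_features_bed()]; `NULL` uses
#'   fixed tiles.
#' @param tile_width Tile width in bp when `features` is `NULL`.
#' @return A list with `cv_mcpg_counts`, `pairwise_correlations` (tibble
#'   with columns `sample_a`, `sample_b`, `correlation`) and
#'   `feature_levels` (per-feature levels per sample).
#' @export
replicate_consistency <- function(call_tables, features = NULL,
                                  tile_width = 1000) {
  if (length(call_tables) < 2) abort("need at least two call tables.")
  if (is.null(names(call_tables))) {
    names(call_tables) <- paste0("sample_", seq_along(call_tables))
  }
  key <- function(x) paste(x$chrom, x$pos, x$strand)
  ref <- key(call_tables[[1]])
  same <- vapply(call_tables, function(x) identical(key(x), ref), TRUE)
  if (!all(same)) {
    abort("all call tables must share the same site universe (chrom, pos, strand).")
  }

  counts <- vapply(call_tables, function(x) sum(x$call == "methylated"), 1)
  cv <- sd(counts) / mean(counts)

  base <- call_tables[[1]]
  feat_id <- if (is.null(features)) {
    paste(base$chrom, floor((base$pos - 1) / tile_width))
  } else {
    assign_features(base, features)
  }

  levels_by <- purrr::imap(call_tables, function(tab, nm) {
    ok <- tab$call != "no_data" & !is.na(feat_id)
    df <- tibble(feature = feat_id[ok], m = tab$call[ok] == "methylated")
    summarise(group_by(df, .data$feature), !!nm := mean(.data$m), .groups = "drop")
  })
  lev <- purrr::reduce(levels_by, function(a, b) {
    dplyr::inner_join(a, b, by = "feature")
  })

  nms <- names(call_tables)
  pairs <- utils::combn(nms, 2)
  cors <- tibble(
    sample_a = pairs[1, ], sample_b = pairs[2, ],
    correlation = apply(pairs, 2, function(p) {
      cor(lev[[p[1]]], lev[[p[2]]])
    })
  )
  list(
    cv_mcpg_counts = cv,
    pairwise_correlations = cors,
    feature_levels = lev
  )
}

# map sites to 0-based half-open BED intervals; NA where uncovered
assign_features <- function(sites, features) {
  out <- rep(NA_character_, nrow(sites))
  for (i in seq_len(nrow(features))) {
    hit <- sites$chrom == features$chrom[i] &
      sites$pos - 1 >= features$start[i] & sites$pos - 1 < features$end[i]
    out[hit] <- sprintf("%s:%d-%d", features$chrom[i], features$start[i], features$end[i])
  }
  out
}

#' Default parameter grid for the simulation benchmark
#'
#' @param mean_cov,pi,clustered,p0,p1 Vectors crossed into a full
#'   factorial grid.
#' @param n_sites,var_factor Scalars shared by every cell.
#' @return A tibble, one row per simulation cell.
#' @export
benchmark_grid <- function(mean_cov = c(3, 6, 9), pi = 0.005,
                           clustered = c(FALSE, TRUE), p0 = 0.002, p1 = 0.7,
                           n_sites = 100000, var_factor = 3) {
  tidyr::expand_grid(
    mean_cov = mean_cov, pi = pi, clustered = clustered, p0 = p0, p1 = p1,
    n_sites = n_sites, var_factor = var_factor
  )
}

#' Simulation benchmark of the Bayes and binomial callers
#'
#' Runs the full factorial simulation study: for every cell of the grid
#' and every replicate, simulates a methylome, applies each caller, and
#' scores it against the planted truth (confusion metrics plus AUC, where
#' the Bayes caller is swept over its raw odds and the binomial caller
#' over its raw p-values).  Reproducible from the master seed.
#'
#' @param grid A tibble of simulation cells, see [benchmark_grid()].
#' @param methods Callers to run (`"bayes"`, `"binomial"`).
#' @param reps Replicates per cell.
#' @param seed Master seed; per-run seeds are derived from it.
#' @param kernel Kernel for the Bayes caller; the default uses the 200
#'   nearest cytosines, the window used in the simulation study.
#' @param w,cutoff,alpha Caller settings.
#' @param estimate_errors If `TRUE` the error rates fed to the callers are
#'   re-estimated from each simulated dataset by EM instead of using the
#'   generating values.
#' @return A tidy tibble, one row per (cell, method, rep), with the
#'   confusion metrics and `auc`.
#' @seealso [summarize_benchmark()], [plot_benchmark()]
#' @examples
#' grid <- benchmark_grid(mean_cov = 3, clustered = TRUE, n_sites = 2000)
#' res <- run_benchmark(grid, reps = 2, seed = 1)
#' summarize_benchmark(res)
#' @export
run_benchmark <- function(grid = benchmark_grid(),
                          methods = c("bayes", "binomial"), reps = 10,
                          seed = NULL,
                          kernel = kernel_spec(mode = "k_nearest", k = 200),
                          w = 0.5, cutoff = 19, alpha = 0.05,
                          estimate_errors = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  seeds <- matrix(
    sample.int(.Machine$integer.max - 1, nrow(grid) * reps),
    nrow = nrow(grid)
  )

  out <- vector("list", nrow(grid) * reps)
  pos <- 0L
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, ]
    for (r in seq_len(reps)) {
      cfg <- sim_config(
        n_sites = cell$n_sites, mean_cov = cell$mean_cov,
        var_factor = cell$var_factor, pi = cell$pi,
        clustered = cell$clustered, p0 = cell$p0, p1 = cell$p1,
        seed = seeds[i, r]
      )
      sim <- simulate_methylome(cfg)
      if (estimate_errors) {
        em <- fit_error_em(sim)
        p0_use <- em$p0_hat
        p1_use <- em$p1_hat
      } else {
        p0_use <- cell$p0
        p1_use <- cell$p1
      }

      res <- list()
      if ("bayes" %in% methods) {
        calls <- classify_bayes(sim, p0_use, p1_use,
          kernel = kernel, w = w, cutoff = cutoff
        )
        res$bayes <- mutate(confusion_metrics(calls, sim$status),
          auc = auc_roc(calls$odds, sim$status, "greater")
        )
      }
      if ("binomial" %in% methods) {
        calls <- classify_binomial(sim, p0_use, alpha = alpha)
        res$binomial <- mutate(confusion_metrics(calls, sim$status),
          auc = auc_roc(calls$p_value, sim$status, "less")
        )
      }
      pos <- pos + 1L
      out[[pos]] <- bind_rows(res, .id = "method") |>
        mutate(cell[rep(1, length(res)), ], rep = r, .before = 1)
    }
  }
  bind_rows(out[seq_len(pos)])
}

#' Summarise a benchmark over replicates
#'
#' Means and Monte-Carlo standard errors of the key metrics per
#' (cell, method).
#'
#' @param results Output of [run_benchmark()].
#' @return A tibble with one row per cell and method.
#' @export
summarize_benchmark <- function(results) {
  cell_cols <- intersect(
    c("mean_cov", "pi", "clustered", "p0", "p1", "n_sites", "var_factor", "method"),
    names(results)
  )
  results |>
    group_by(across(dplyr::all_of(cell_cols))) |>
    summarise(
      reps = n(),
      across(
        dplyr::all_of(c(
          "sensitivity", "one_minus_specificity_sparse",
          "specificity_standard", "accuracy_weighted", "auc"
        )),
        list(
          mean = ~ mean(.x, na.rm = TRUE),
          se = ~ sd(.x, na.rm = TRUE) / sqrt(sum(!is.na(.x)))
        )
      ),
      .groups = "drop"
    )
}

#' Bar-panel plot of benchmark sensitivities
#'
#' @param results Output of [run_benchmark()].
#' @param metric Which metric to plot.
#' @return A ggplot object: bars per method, panels per coverage, fill by
#'   genome type.
#' @export
plot_benchmark <- function(results, metric = "sensitivity") {
  summ <- summarize_benchmark(results)
  mcol <- paste0(metric, "_mean")
  scol <- paste0(metric, "_se")
  summ$genome <- ifelse(summ$clustered, "clustered", "homogeneous")
  ggplot2::ggplot(summ, ggplot2::aes(
    x = .data$method, y = .data[[mcol]], fill = .data$genome
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data[[mcol]] - .data[[scol]],
        ymax = .data[[mcol]] + .data[[scol]]
      ),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25
    ) +
    ggplot2::facet_grid(
      ggplot2::vars(.data$pi), ggplot2::vars(.data$mean_cov),
      labeller = ggplot2::label_both
    ) +
    ggplot2::labs(x = NULL, y = metric)
}
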