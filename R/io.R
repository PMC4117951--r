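#' Read a per-cytosine count table
#'
#' Supports two dialects: (a) a generic six-column TSV — `chrom`, `pos`
#' (1-based), `strand`, `context`, `n_meth`, `n_total`; (b) a
#' Bismark-style cytosine report — `chrom`, `pos`, `strand`,
#' `count_methylated`, `count_unmethylated`, `context`, `trinucleotide`
#' (total reads = methylated + unmethylated, `CG` normalised to `CpG`).
#' Neither dialect carries a header line.  The result is validated and
#' sorted; malformed rows, counts with `n_meth > n_total` and duplicated
#' sites are rejected with the offending line number.
#'
#' @param path Path to the file.
#' @param format `"auto"` (decide by column count: 7 columns means
#'   Bismark), `"tsv"` or `"bismark"`.
#' @param context Keep only sites of this context (default `"CpG"`);
#'   `NULL` keeps everything.
#' @return A sorted count-table tibble (see [meth_sites()]) with the
#'   source path and dialect attached as attributes.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("chr1\t100\t+\tCpG\t3\t4", "chr1\t250\t-\tCpG\t0\t2"), tf)
#' read_counts(tf)
#' @export
read_counts <- function(path, format = c("auto", "tsv", "bismark"),
                        context = "CpG") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path,
    col_names = FALSE, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  if (format == "auto") {
    format <- if (ncol(raw) >= 7) "bismark" else "tsv"
  }

  num <- function(x, col) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x) | is.na(x))
    if (length(bad) > 0) {
      abort(sprintf(
        "malformed %s field at line %d of %s.", col, bad[1], path
      ))
    }
    v
  }

  sites <- if (format == "tsv") {
    if (ncol(raw) < 6) abort(sprintf("expected 6 columns in generic TSV %s.", path))
    tibble(
      chrom = raw[[1]], pos = num(raw[[2]], "pos"), strand = raw[[3]],
      context = raw[[4]], n_meth = num(raw[[5]], "n_meth"),
      n_total = num(raw[[6]], "n_total")
    )
  } else {
    if (ncol(raw) < 6) abort(sprintf("expected >= 6 columns in Bismark report %s.", path))
    n_m <- num(raw[[4]], "count_methylated")
    n_u <- num(raw[[5]], "count_unmethylated")
    tibble(
      chrom = raw[[1]], pos = num(raw[[2]], "pos"), strand = raw[[3]],
      context = ifelse(raw[[6]] == "CG", "CpG", raw[[6]]),
      n_meth = n_m, n_total = n_m + n_u
    )
  }

  bad <- which(sites$n_meth > sites$n_total | sites$n_meth < 0 |
    sites$n_total < 0 | sites$pos < 1)
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid counts (need 0 <= n_meth <= n_total, pos >= 1) at line %d of %s.",
      bad[1], path
    ))
  }
  if (!is.null(context)) sites <- filter(sites, .data$context == !!context)
  out <- validate_sites(sites)
  attr(out, "source") <- path
  attr(out, "dialect") <- format
  out
}

#' Write a count table in the generic TSV dialect
#'
#' Emits the six-column, headerless TSV accepted back by [read_counts()]
#' and by every classifier entry point.
#'
#' @param sites A count table.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_counts <- function(sites, path) {
  sites <- validate_sites(sites)
  readr::write_tsv(
    tibble(
      sites$chrom, format(sites$pos, scientific = FALSE, trim = TRUE),
      sites$strand, sites$context, sites$n_meth, sites$n_total
    ),
    path,
    col_names = FALSE
  )
  invisible(path)
}

#' Write per-site calls as TSV
#'
#' One row per input site (no silent drops) with columns `chrom`, `pos`,
#' `strand`, `context`, `n_meth`, `n_total`, `p_value`, `q_value`,
#' `prior`, `odds`, `call`.  Floating statistics are written at six
#' significant digits; statistics undefined at zero-coverage sites are
#' left empty, not set to 0 or 1.
#'
#' @param calls A call table from [classify_bayes()] or
#'   [classify_binomial()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_calls <- function(calls, path) {
  cols <- c(
    "chrom", "pos", "strand", "context", "n_meth", "n_total",
    "p_value", "q_value", "prior", "odds", "call"
  )
  missing <- setdiff(cols, names(calls))
  if (length(missing) > 0) {
    abort(sprintf("`calls` is missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  out <- calls[, cols]
  for (col in c("p_value", "q_value", "prior", "odds")) {
    out[[col]] <- signif(out[[col]], 6)
  }
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Read back a call table written by [write_calls()]
#'
#' @param path Path to the TSV.
#' @return The call-table tibble.
#' @export
read_calls <- function(path) {
  readr::read_tsv(path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      chrom = readr::col_character(), strand = readr::col_character(),
      context = readr::col_character(), call = readr::col_character(),
      .default = readr::col_double()
    )
  )
}

#' Write methylated sites as a BED file
#'
#' Each methylated call becomes a 0-based half-open interval of width 1
#' (a site at 1-based position 100 gives `start = 99`, `end = 100`).
#'
#' @inheritParams write_calls
#' @return The path, invisibly.
#' @export
write_calls_bed <- function(calls, path) {
  m <- filter(calls, .data$call == "methylated")
  gr <- GenomicRanges::GRanges(
    seqnames = m$chrom,
    ranges = IRanges::IRanges(start = m$pos, width = 1),
    strand = ifelse(m$strand %in% c("+", "-"), m$strand, "*")
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write a smoothed methylation track as bedGraph
#'
#' @param track Output of [smooth_track()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  ok <- !is.na(track$level)
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom[ok],
    ranges = IRanges::IRanges(start = track$pos[ok], width = 1),
    score = track$level[ok]
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read BED intervals as a feature table
#'
#' @param path Path to a BED file.
#' @return A tibble with `chrom`, `start`, `end` (0-based half-open), for
#'   use with [replicate_consistency()].
#' @export
read_features_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Merge symmetric CpG strand pairs
#'
#' Sums the counts of a plus-strand CpG at position `p` with its
#' minus-strand partner at `p + 1` into a single plus-strand record.
#' Unpaired sites are kept as they are.
#'
#' @param sites A count table with strand information.
#' @return The merged count table.
#' @export
merge_cpg_strands <- function(sites) {
  sites <- validate_sites(sites)
  plus <- filter(sites, .data$strand == "+")
  minus <- filter(sites, .data$strand == "-")
  other <- filter(sites, !.data$strand %in% c("+", "-"))

  j <- left_join(
    plus,
    select(
      mutate(minus, pos = .data$pos - 1),
      "chrom", "pos",
      m_meth = "n_meth", m_total = "n_total"
    ),
    by = c("chrom", "pos")
  )
  merged <- mutate(j,
    n_meth = .data$n_meth + dplyr::coalesce(.data$m_meth, 0),
    n_total = .data$n_total + dplyr::coalesce(.data$m_total, 0)
  ) |>
    select(-"m_meth", -"m_total")

  paired_minus_key <- paste(j$chrom, j$pos + 1)[!is.na(j$m_total)]
  lone_minus <- filter(minus, !paste(.data$chrom, .data$pos) %in% paired_minus_key)
  validate_sites(bind_rows(merged, lone_minus, other))
}
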