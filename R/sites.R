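#' Build a per-cytosine count table
#'
#' Constructs the tibble of per-site bisulfite counts used throughout the
#' package: one row per cytosine with its genomic coordinates, the number of
#' "C" (methylated-looking) reads and the total read count.  Rows are sorted
#' by chromosome and position and all count invariants are checked.
#'
#' @param chrom Chromosome / scaffold names.
#' @param pos 1-based genomic positions.
#' @param n_meth Number of methylated ("C") reads at each site.
#' @param n_total Total number of reads at each site (may be 0).
#' @param strand Strand, one of `"+"`, `"-"`, `"."` (recycled).
#' @param context Cytosine context, `"CpG"`, `"CHG"` or `"CHH"` (recycled).
#'
#' @return A tibble with columns `chrom`, `pos`, `strand`, `context`,
#'   `n_meth`, `n_total`, sorted by `(chrom, pos, strand)`.
#' @examples
#' meth_sites("chr1", c(100, 250), n_meth = c(3, 0), n_total = c(4, 2))
#' @export
meth_sites <- function(chrom, pos, n_meth, n_total, strand = ".",
                       context = "CpG") {
  validate_sites(tibble(
    chrom = as.character(chrom), pos = as.numeric(pos),
    strand = strand, context = context,
    n_meth = as.numeric(n_meth), n_total = as.numeric(n_total)
  ))
}

# Validate (and normalise) a site table: required columns, invariants,
# uniqueness, sort order.  Extra columns are carried through untouched.
validate_sites <- function(sites, arg = "sites") {
  if (!is.data.frame(sites)) {
    abort(sprintf("`%s` must be a data frame of per-site counts.", arg))
  }
  required <- c("chrom", "pos", "n_meth", "n_total")
  missing <- setdiff(required, names(sites))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s.", arg,
      paste0("`", missing, "`", collapse = ", ")
    ))
  }
  sites <- as_tibble(sites)
  if (!"strand" %in% names(sites)) sites$strand <- "."
  if (!"context" %in% names(sites)) sites$context <- "CpG"
  sites$pos <- as.numeric(sites$pos)
  sites$n_meth <- as.numeric(sites$n_meth)
  sites$n_total <- as.numeric(sites$n_total)

  bad <- which(!is.finite(sites$pos) | sites$pos < 1 |
    !is.finite(sites$n_meth) | !is.finite(sites$n_total) |
    sites$n_meth < 0 | sites$n_total < 0 | sites$n_meth > sites$n_total)
  if (length(bad) > 0) {
    abort(sprintf(
      "`%s` violates count invariants (pos >= 1, 0 <= n_meth <= n_total) at row(s) %s.",
      arg, paste(head(bad, 5L), collapse = ", ")
    ))
  }
  key <- paste(sites$chrom, sites$pos, sites$strand)
  if (anyDuplicated(key) > 0) {
    abort(sprintf(
      "`%s` contains duplicated sites (chrom, pos, strand), e.g. %s.",
      arg, key[anyDuplicated(key)]
    ))
  }
  arrange(sites, .data$chrom, .data$pos, .data$strand)
}

# fractional methylation, NA where there is no coverage
frac_meth <- function(n_meth, n_total) {
  ifelse(n_total > 0, n_meth / n_total, NA_real_)
}
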