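Package: methclass
Title: Bayesian Classification of Cytosine Methylation Status from
    Bisulfite Sequencing Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Calls per-cytosine methylation status from whole-genome
    bisulfite sequencing count tables with a posterior-odds Bayes
    classifier that corrects for incomplete bisulfite conversion
    (non-conversion) and spurious conversion of methylated cytosines
    (over-conversion), and that borrows strength from the spatially
    correlated methylation levels of neighbouring CpGs through a kernel
    local prior. Includes the widely used binomial caller with false
    discovery rate correction as a baseline, an expectation-maximisation
    estimator of the conversion error rates from a two-component binomial
    mixture, spatial autocorrelation curves with data-driven kernel
    bandwidth selection, kernel-smoothed methylation tracks, a synthetic
    methylome simulator with shifted negative-binomial coverage and
    clustered methylation, and benchmarking utilities (sensitivity,
    specificity, ROC/AUC, coverage downsampling, replicate consistency).
    Designed for sparsely methylated genomes, such as those of many
    invertebrates and plants, where low coverage and low genome-wide
    methylation make the binomial test underpowered.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    optparse,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
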