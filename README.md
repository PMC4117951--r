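# methclass

Binary methylation calls from whole-genome bisulfite sequencing
("methylC-seq") count data, built for **sparsely methylated genomes** —
invertebrates, many plants — where global CpG methylation is well under 1%,
coverage is low and overdispersed, and the standard binomial caller loses
most low-coverage methylated sites.

## The problem and the model

Bisulfite conversion reads non-methylated C as T and methylated C as C,
imperfectly: a non-methylated C survives as C with the *non-conversion*
rate p0, and a methylated C reads as C only with probability
p1 = 1 − over-conversion. The widely used binomial caller tests
H0 "site unmethylated" (k C reads out of N, success rate p0) and corrects
the genome-wide family with the Benjamini–Hochberg FDR. Under BH, a site
with p-value p can only ever be rejected when its p-value percentile —
which tracks the genome-wide methylation level — reaches p/α: a single
C read (p ≈ 0.002) needs a 4% methylated genome, one C with two T reads
about 12%. Sparse methylomes never get there, so low-coverage methylated
sites are systematically called negative.

`methclass` instead computes **posterior odds** of methylation from a
two-state model,

```
odds = prior/(1 − prior) · p1^k (1−p1)^(N−k) / [ p0^k (1−p0)^(N−k) ]
```

and calls a site methylated when odds ≥ 19 (posterior probability ≥ 0.95,
i.e. < 0.05 chance the call is false — the analogue of q < 0.05). The
prior exploits the kilobase-scale spatial clustering of CpG methylation:
it mixes the error-corrected **global** level π_G with a kernel-weighted
**local** level π_L of the focal site's neighbourhood
(triangle kernel, bandwidth 1.5 kb or the 200 nearest CpGs, K(0) = 0 so a
site never informs its own prior), as π_C = (1−w)·π_G + w·π_L with
w = 0.5 by default.

The package also provides:

* `fit_error_em()` — EM estimation of (p0, p1, π) from a two-component
  binomial mixture, with broom-style `tidy()`/`glance()` methods;
* `classify_binomial()` — the binomial/FDR baseline;
* `correlation_curve()` / `select_bandwidth()` — spatial autocorrelation
  of methylation versus distance and data-driven kernel bandwidth;
* `smooth_track()` — kernel-smoothed methylation tracks (bedGraph export);
* `simulate_methylome()` — synthetic methylomes with shifted
  negative-binomial coverage (variance ≈ 3× mean, minimum 1 read) and
  homogeneous or clustered methylation;
* `run_benchmark()`, `downsample_experiment()`,
  `replicate_consistency()`, `auc_roc()` — the evaluation protocol
  (sensitivity, the sparse-methylome error ratio FP / #truly-methylated,
  ROC/AUC, coverage downsampling, replicate consistency);
* a command line (`inst/cli/methclass`) with `simulate`, `fit-errors`,
  `classify`, `binomial`, `spatial` and `evaluate` subcommands.

Input is the generic 6-column count TSV (`chrom pos strand context
n_meth n_total`) or a Bismark-style cytosine report (`read_counts()`).

## Worked example

A clustered sparse methylome (20,000 CpGs, mean coverage 3, global level
2%, methylation concentrated in 1/10 of the genome at 10× intensity),
error rates re-estimated from the data, then both callers:

```r
library(methclass)
library(dplyr)

cfg <- sim_config(n_sites = 20000, mean_cov = 3, pi = 0.02,
                  clustered = TRUE, seed = 7)
sim <- simulate_methylome(cfg)

fit <- fit_error_em(sim)
tidy(fit)
#> # A tibble: 3 × 2
#>   term  estimate
#>   <chr>    <dbl>
#> 1 p0     0.00245
#> 2 p1     0.683
#> 3 pi     0.0195

bayes <- classify_bayes(sim, p0 = fit$p0_hat, p1 = fit$p1_hat,
                        kernel = kernel_spec(mode = "k_nearest", k = 200))
binom <- classify_binomial(sim, p0 = fit$p0_hat)

bind_rows(bayes    = confusion_metrics(bayes, sim$status),
          binomial = confusion_metrics(binom, sim$status), .id = "method") |>
  select(method, tp, fp, fn, sensitivity, one_minus_specificity_sparse)
#> # A tibble: 2 × 6
#>   method      tp    fp    fn sensitivity one_minus_specificity_sparse
#>   <chr>    <int> <int> <int>       <dbl>                       <dbl>
#> 1 bayes      249     0   164       0.603                           0
#> 2 binomial   153     0   260       0.370                           0

auc_roc(bayes$odds, sim$status)            # 0.9943
auc_roc(binom$p_value, sim$status, "less") # 0.9120
```

The EM recovers the generating error rates (p0 = 0.002, p1 = 0.7,
π = 0.02) from counts alone. The posterior-odds caller finds 96 truly
methylated sites covered by a single C read inside methylated
neighbourhoods — the binomial caller finds none of them (its single-read
q-values cannot clear 0.05 in a 2%-methylated genome) — while making zero
false methylated calls; sensitivity rises from 0.370 to 0.603 at the same
error level, and the AUC gap (0.994 vs 0.912) shows the ranking itself is
better, independent of the cutoff.

Equivalent shell usage:

```sh
methclass simulate --n-sites 20000 --mean-cov 3 --pi 0.02 --clustered \
    --seed 7 --out counts.tsv
methclass fit-errors --counts counts.tsv --out errors.json
methclass classify --counts counts.tsv --errors errors.json \
    --k-nearest 200 --out calls.tsv
```

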