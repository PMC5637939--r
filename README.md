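# eqtlmap

Simultaneous mapping of multiple gene/variant associations (eQTLs) from
paired genotype and RNA-seq data, in a sparse Bayesian
multiple/multivariate regression framework.

Given an N x M genotype dosage matrix **X** (0/1/2 minor-allele counts)
and an N x K read-count matrix **Z**, `eqtlmap` estimates the full M x K
coefficient matrix **B** — every marker against every transcript at once
— under the three-level shrinkage prior

    beta_jk ~ N(0, 1 / (tau_k * zeta_jk * eta_j)),

with Jeffreys hyperpriors on all precisions. Small marker-level `eta_j`
flags a hotspot variant, small transcript-level `tau_k` a polygenic
transcript. Four likelihoods share this prior and are estimated by Gibbs
sampling:

| model    | likelihood                           | device                               |
|----------|--------------------------------------|--------------------------------------|
| `normal` | Gaussian on transformed counts       | fully conjugate                      |
| `pois`   | Poisson-LogNormal mixture            | Metropolis-within-Gibbs latents      |
| `bin`    | over-dispersed Binomial              | Polya-Gamma augmentation             |
| `nbin`   | Negative Binomial                    | Polya-Gamma augmentation, closed-form coefficient conditional |

The Polya-Gamma device is what makes Bayesian multivariate Negative
Binomial regression tractable here: with auxiliaries
`omega_ik ~ PG(z_ik + r_k, psi_ik)` the coefficient conditional becomes
multivariate Normal with precision `A_k = X' diag(omega) X + prior` —
see the methods vignette (`vignettes/eqtl-mapping-models.Rmd`) for the
full account.

The package also provides the transformation suite feeding the Normal
model (log, per-transcript Box-Cox, Blom normal scores, and Laplace
smoothing followed by arcsin or logit), a simulator of
genotype/count/effect triplets, the benchmarking metrics (Matthews
correlation, RMSE among true positives, Lin's concordance) and a Monte
Carlo cross-validation harness.

## Worked example

```r
library(eqtlmap)

# simulate a small cohort: 250 samples, 20 markers, 100 transcripts,
# 10 planted associations on the log scale
cfg <- simulation_config(n = 250, m = 20, k = 100, n_assoc = 10, seed = 2)
dat <- simulate_dataset(cfg)

# fit the Normal model on arcsin-transformed, Laplace-smoothed counts
y   <- transform_counts(dat$counts, "arcsin")
fit <- fit_normal(dat$genotypes, y, mcmc_control(2000, 1000, seed = 1))
fit
#> <eqtl_fit: normal model (arcsin), 20 markers x 100 transcripts>
#>   1000 retained draws (2000 sweeps, 1000 burn-in), seed 1
#>   associations called at 2.5 robust SDs: 10

tidy(fit) |> dplyr::filter(called) |> dplyr::arrange(-abs(beta_median))
#> # A tibble: 10 x 6
#>   marker_id transcript_id beta_median beta_lo beta_hi called
#> 1 marker17  transcript94       0.0650  0.0622  0.0676 TRUE
#> 2 marker12  transcript20       0.0485  0.0365  0.0615 TRUE
#> 3 marker10  transcript36       0.0407  0.0369  0.0447 TRUE
#> # ...

# score against the planted truth
benchmark_fit(fit, dat$truth)
#> # A tibble: 1 x 10
#>   model  transform  n_tp  n_fp  n_fn  n_tn   tpr   ppv   mcc rmse_tp
#> 1 normal arcsin       10     0     0  1990     1     1     1   0.248

# the Negative Binomial model works on the raw counts directly
benchmark_fit(fit_nbin(dat$genotypes, dat$counts,
                       mcmc_control(2000, 1000, seed = 2)), dat$truth)
#> # A tibble: 1 x 10
#>   model transform  n_tp  n_fp  n_fn  n_tn   tpr   ppv   mcc rmse_tp
#> 1 nbin  none          9     0     1  1990   0.9     1 0.948  0.0531
```

All ten planted effects are recovered with no false call by the arcsin
model (the Negative Binomial misses the weakest one); `beta_median` is
on the arcsin-probability scale, so magnitudes are small but their
posterior signal-to-noise drives the calls. `monte_carlo_cv()` scores
held-out predictive concordance for any of the models.

A thin command-line interface wraps the same functions:

```sh
exec/eqtlmap simulate --n 250 --m 20 --k 100 --n-assoc 10 --seed 1 --out sim/
exec/eqtlmap run --model normal --transform arcsin \
    --genotypes sim/genotypes.tsv --expression sim/counts.tsv \
    --iters 2000 --burnin 1000 --seed 1 --out fit/
```

Genotypes load from TSV or bi-allelic VCF (`--vcf`; GT dosages, flipped
to minor-allele counts, multi-allelic records skipped), with the
standard filters (MAF strictly above 5%, mean count at least 10)
applied via `filter_markers()` / `filter_transcripts()`.

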