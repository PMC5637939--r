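---
title: "Sparse Bayesian eQTL mapping: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse Bayesian eQTL mapping: models, priors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

An expression quantitative trait locus (eQTL) is a genetic variant whose
genotype is associated with the expression of one or more genes. Given an
N x M genotype dosage matrix **X** (entries 0/1/2, the minor-allele count
per sample and marker) and an N x K matrix **Z** of RNA-seq read counts,
`eqtlmap` estimates the M x K coefficient matrix **B** linking every
marker to every transcript *simultaneously*, rather than testing each
pair separately. Joint estimation captures synergistic effects of several
variants on one transcript and shares evidence across transcripts, at the
price of a harder inference problem: most of **B** must be exactly
irrelevant, and the likelihood for count data is not Gaussian.

## The shared sparsity prior

All four models place the same three-level Normal scale-mixture prior on
each coefficient:

$$\beta_{jk} \sim \mathcal N\!\left(0,\; \tau_k^{-1}\,\zeta_{jk}^{-1}\,\eta_j^{-1}\right),$$

with improper Jeffreys priors $p(\theta) \propto 1/\theta$ on every
precision. The decomposition is interpretable: a small marker-level
$\eta_j$ marks a *hotspot* (one variant driving many transcripts), a
small transcript-level $\tau_k$ marks a *polygenic* transcript, and
$\zeta_{jk}$ refines individual pairs. Jeffreys priors are parameter-free
and strongly sparsity-inducing; their Gamma full conditionals are the
standard conjugate forms

$$\tau_k \sim \Gamma\!\big(M/2,\ \tfrac12\textstyle\sum_j \zeta_{jk}\eta_j\beta_{jk}^2\big),\quad
\eta_j \sim \Gamma\!\big(K/2,\ \tfrac12\textstyle\sum_k \tau_k\zeta_{jk}\beta_{jk}^2\big),\quad
\zeta_{jk} \sim \Gamma\!\big(\tfrac12,\ \tfrac12\tau_k\eta_j\beta_{jk}^2\big).$$

Because the prior is improper these conditionals are heavy-tailed; draws
are clipped to $[10^{-12}, 10^{12}]$ to avoid numerical overflow. For a
fully irrelevant row or column the three precisions perform a
multiplicative random walk upward until they hit the clip bound, which is
exactly the intended behaviour: the coefficient is pinned to zero at
machine scale. The clip bounds never bind for coefficients with real
data support.

Under every likelihood below, the conditional posterior of a transcript's
coefficient vector $\beta_k$ is multivariate Normal with precision
$A_k$ and mean $m_k$, computed by `compute_beta_posterior()` and sampled
through a Cholesky factorization (never an explicit inverse; a failed
factorization is retried once with a $10^{-8}$ ridge).

## The four likelihoods

* **normal** — $y_{ik} \sim \mathcal N(\mu_k + x_i'\beta_k,\ \tau_k^{-1})$
  on transformed expression. The residual precision is $\tau_k$ itself,
  shared with the prior scale, so
  $A_k = \tau_k (X'X + \mathrm{diag}(\zeta_k \circ \eta))$ and the
  conditional mean is the ridge solution
  $(X'X + \mathrm{diag}(\zeta_k \circ \eta))^{-1} X' y_k$. Sharing
  $\tau_k$ keeps the model fully conjugate with exactly the three
  precision parameters; the residual sum of squares is folded into the
  $\tau_k$ conditional (shape $+N/2$, rate $+\mathrm{RSS}_k/2$).
* **pois** — an over-dispersed Poisson, i.e. a Poisson-LogNormal
  mixture: $z_{ik} \sim \mathrm{Pois}(e^{y_{ik} + o_i})$ with latent
  $y_{ik} \sim \mathcal N(\mu_k + x_i'\beta_k, \sigma_k^2)$ and log
  size-factor offsets $o_i$. The latent variance $\sigma_k^2$ carries
  the over-dispersion and has a conjugate inverse-Gamma(1, 1) prior.
  The latents have no conjugate update and use per-entry adaptive
  random-walk Metropolis (target acceptance 0.4, adaptation during
  burn-in only, Robbins-Monro decay $t^{-0.55}$).
* **bin** — an over-dispersed Binomial:
  $z_{ik} \sim \mathrm{Bin}(n_i, \mathrm{logit}^{-1}(y_{ik}))$ with
  $n_i$ the sample's library size and the same logit-Normal mixing.
  Polya-Gamma auxiliaries $\omega_{ik} \sim \mathrm{PG}(n_i, y_{ik})$
  make the latents conditionally Normal, so the whole sweep is Gibbs.
* **nbin** — Negative Binomial:
  $z_{ik} \sim \mathrm{NB}(r_k, p_{ik})$ with log-odds
  $\psi_{ik} = \mu_k + o_i + x_i'\beta_k$ (conditional mean
  $r_k e^{\psi_{ik}}$). Polya-Gamma auxiliaries
  $\omega_{ik} \sim \mathrm{PG}(z_{ik} + r_k, \psi_{ik})$ yield Gaussian
  pseudo-data $(z_{ik} - r_k)/(2\omega_{ik})$ with precisions
  $\omega_{ik}$, giving the closed-form $\beta_k$ conditional that makes
  Bayesian NB regression tractable. The dispersion $r_k$ moves by
  adaptive random-walk Metropolis on $\log r_k$.

### The Negative Binomial dispersion prior

The NB likelihood is flat along the Poisson limit: $r_k \to \infty$ with
$\mu_k$ compensating leaves the fit unchanged. With a flat prior on
$\log r_k$ the posterior is therefore improper on near-Poisson
transcripts and the dispersion chain drifts without bound (we observed
Geweke z-scores near 20 before adding a prior). `fit_nbin()` places a
weakly informative Gamma(2, rate 0.1) prior on $r_k$ (mean 20, sd 14),
which is dominated by the data whenever the data carry dispersion
information and merely pins the ridge otherwise.

### Offsets

Sequencing depth enters as known per-sample offsets: log size factors
for `pois`/`nbin` and the library-size denominators for `bin`. The
default size-factor estimator is median-of-ratios rather than total
count: when one strongly genotype-driven transcript contributes a large
share of the library, the total count itself becomes genotype-dependent
through composition, and a total-count offset feeds that marker's
signal back into every transcript (we measured row-wide false
associations and even performance *decreasing* with sample size under
total-count offsets at K = 100 with a dominant effect gene; the
median-of-ratios estimator, which follows the unaffected majority of
transcripts, removes the artifact). Total-count factors remain
available through `size_factors()`, and both count fitters accept
user-supplied offsets (`offset=`, `lib_sizes=`). For the same reason, a
correctly specified recovery experiment at small K must condition on
the offsets that generated the data; with genome-scale K the
distinction fades. The Binomial model's library-size denominators are
part of its definition and keep the compositional coupling — one reason
it trails the other models in benchmarks.

## Transformations for the Normal model

* `log` — $\log(z + 1)$ (natural log; the pseudo-count avoids
  $\log 0$).
* `boxcox` — per-transcript one-parameter Box-Cox on $z + 1$, with
  $\lambda_k$ maximizing the profile log-likelihood over $[-2, 2]$
  (golden-section search; the $\lambda = 0$ limit reproduces `log`
  exactly). Per-transcript estimation accommodates gene-wise
  mean-variance heterogeneity.
* `blom` — rank-based inverse-normal scores
  $\Phi^{-1}\big((r_i - 3/8)/(N + 1/4)\big)$ with average ranks for
  ties; the classical Blom constants. Depends on ranks only.
* `arcsin`, `logit` — Laplace (additive) smoothing first: viewing a
  sample's library as a multinomial assignment of reads to K
  transcripts, $p_{ik} = (z_{ik} + c)/(\sum_k z_{ik} + cK)$ with $c = 1$.
  Rows sum to one and every entry lies between the empirical proportion
  and the uniform $1/K$. The smoothed proportions then pass through
  $\arcsin\sqrt{p}$ (variance-stabilizing) or $\log\frac{p}{1-p}$.
  Counts may optionally be total-count normalized before smoothing
  (`normalize = TRUE`); the default is off, since smoothing already
  conditions on the library size.

Externally transformed matrices (e.g. precision-weighted or
variance-stabilized output of dedicated RNA-seq tools) can be supplied
directly to `fit_normal()` via `transform = "none"` semantics; those
transformations are intentionally not reimplemented here.

## Calling associations

Each pair is summarized by its posterior median $\hat\beta_{jk}$ and
called when $|\hat\beta_{jk}| > 2.5\, s_{jk}$, where
$s_{jk} = \mathrm{MAD}(\text{draws}_{jk})/0.6745$ is the per-coefficient
robust posterior SD. We initially evaluated a single scale pooled across
all $M K$ posterior medians, but under this prior the pooled scale is
degenerate by construction: the majority of medians sit at the shrinkage
spike (~$10^{-13}$ and spanning orders of magnitude), so any pooled
quantile is arbitrary and the rule collapses to "call everything that is
not exactly zero". The per-coefficient scale turns the rule into a
posterior signal-to-noise test that is invariant to the many orders of
magnitude the shrinkage spans; the threshold (2.5 robust SDs) is exposed
as `call_threshold`/`--call-threshold`.

## The simulator

`simulate_dataset()` generates (X, Z, B) triplets that emulate the
statistical structure of population panels without template downloads:

* marker MAFs $\sim$ Uniform(0.05, 0.5), dosages Binomial(2, maf)
  (Hardy-Weinberg);
* per-gene base means LogNormal(log 100, 1) and NB dispersions
  Gamma(2, rate 0.2) — chosen to reproduce the skewed mean distribution
  and mean-variance relationship typical of bulk RNA-seq count tables;
* effect magnitudes Exponential(rate 1) with fair random signs, placed
  uniformly and/or in hotspot (one marker, 10% of transcripts) and
  polygenic (one transcript, 10% of markers) patterns;
* effects act multiplicatively on the NB mean through $e^{x\beta}$ with
  mean-centered dosages, so simulated and fitted coefficients share the
  log scale;
* optional noise: resampling genotype entries from their marker's dosage
  distribution, and multiplying count entries by Uniform(1/10, 10)
  outlier factors.

What the simulator does **not** emulate: linkage disequilibrium between
markers, GC/length biases, batch effects, correlated expression modules
and zero inflation. Passing recovery tests on simulated data therefore
demonstrates correctness of the inference machinery under the stated
generating assumptions, not performance on any particular real cohort.

## Numerical and MCMC choices

* Default chains: 4000 sweeps, first 2000 discarded, single chain, no
  thinning; every fit is an exact deterministic function of (inputs,
  seed, settings).
* Genotypes are mean-centered inside every fitter (the prior is
  zero-centered); per-transcript intercepts absorb location.
* Polya-Gamma draws: Devroye's exact rejection sampler for unit shapes,
  summed for integer shapes below 8; fractional shapes use a 50-term
  truncated series with the analytic tail mean added; shapes >= 8 use a
  shifted-Gamma approximation matching the exact mean, variance and
  skewness (relative third-moment truncation error < 1e-5 and the
  approximation tends to the exact Normal limit as the shape grows). A
  pure-R truncated-series reference sampler is retained for
  cross-checks.
* Adaptive Metropolis steps adapt only during burn-in (so retained draws
  come from a fixed kernel), with target acceptance 0.4.
* Degenerate inputs: constant transcripts get a zero Box-Cox column
  (with a warning), all-zero transcripts are absorbed by the intercept,
  an all-zero coefficient matrix floors the Gamma rates at $10^{-12}$.

## Validation strategy and problem sizes

The test suite validates each layer against an independent oracle: the
coefficient conditional against a dense ridge solve; Polya-Gamma moments
against the closed forms $(b/2c)\tanh(c/2)$; precision conditionals
against Gamma means; the metrics against confusion-matrix /
textbook-formula recomputations; and each full sampler against
(i) Geweke drift z-scores on a 3-marker, 2-transcript toy posterior
(|z| < 4 over 5000 post-warm-up sweeps; the warm-up lets the NB
dispersion walk forget its moment-based initialization), (ii) recovery
of planted effects from correctly specified self-simulated data
(N = 300-500, M = 10, K = 20, 5 effects of magnitude 1; MCC >= 0.8),
(iii) a null calibration (20 seeded null datasets per model, at most 5%
with any call), and (iv) a scaled-down benchmark (M = 20, K = 100, 10
effects, 3 seeds at N = 100 and 400) checking the qualitative orderings:
performance improves with sample size for every model, the
arcsin-Normal model leads at small N, the Binomial model trails, and
the Poisson mixture performs on par with the Negative Binomial. The
compact sizes keep the full suite to minutes on one core while leaving
each check's conclusion unchanged at larger scale.

## Known limitations

* Single-chain inference; the Geweke diagnostic is the only built-in
  convergence check. For publication-grade analyses run several seeds.
* The three-level prior shares strength across rows and columns, so a
  strong hotspot inflates the posterior spread of its row's null pairs;
  the signal-to-noise calling rule compensates but very weak effects on
  hotspot markers are the hardest case.
* Transcripts are conditionally independent given X; co-expression not
  induced by genotype is not modelled.
* Phased/haplotype genotypes, dosage uncertainty and variant
  annotation pipelines are out of scope; genotype input is the 0/1/2
  dosage matrix (TSV or bi-allelic GT-field VCF).
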