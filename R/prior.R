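#' Shrinkage hyperparameter state
#'
#' The three-level sparsity prior puts `beta_jk ~ N(0, 1 / (tau_k zeta_jk
#' eta_j))`, with an improper Jeffreys prior on every precision. `tau_k` is
#' transcript-specific (a small value flags a polygenic transcript),
#' `eta_j` marker-specific (a small value flags a hotspot marker) and
#' `zeta_jk` refines the pair.
#'
#' @param m,k numbers of markers and transcripts.
#' @param tau,eta,zeta optional initial values (defaults: all 1).
#' @return a list with components `tau` (length K), `eta` (length M) and
#'   `zeta` (M x K), class `precision_state`.
#' @export
precision_state <- function(m, k, tau = rep(1, k), eta = rep(1, m),
                            zeta = matrix(1, m, k)) {
  stopifnot(length(tau) == k, length(eta) == m,
            all(dim(zeta) == c(m, k)),
            all(is.finite(tau)), all(tau > 0),
            all(is.finite(eta)), all(eta > 0),
            all(is.finite(zeta)), all(zeta > 0))
  structure(list(tau = tau, eta = eta, zeta = zeta),
            class = "precision_state")
}

#' Conditional posterior of one transcript's coefficient vector
#'
#' For transcript k the conditional posterior of `beta_k` is multivariate
#' Normal with precision matrix `A_k` and mean `m_k`. With Gaussian
#' (pseudo-)data of unit conditional variance and observation weights `w`
#' (all ones for the Normal model, Polya-Gamma draws for the Negative
#' Binomial, `1 / sigma_k^2` for the latent-Normal Poisson/Binomial
#' updates):
#' `A_k = X' diag(w) X + diag(tau_k * zeta_k * eta)` and
#' `m_k = A_k^{-1} X' diag(w) resp`. The Normal model shares `tau_k`
#' between residual precision and prior, giving
#' `A_k = tau_k (X'X + diag(zeta_k * eta))` with the same (tau-free) mean.
#' Systems are solved through a Cholesky factorization, never an explicit
#' inverse; a failed factorization is retried once with a `1e-8` ridge.
#'
#' @param x centered genotype matrix (N x M, numeric).
#' @param resp length-N response (residual) vector on the pseudo-data scale.
#' @param weights length-N positive observation weights.
#' @param tau_k transcript-level precision (scalar).
#' @param zeta_k length-M pair precisions for this transcript.
#' @param eta length-M marker precisions.
#' @param normal if `TRUE` use the Normal-model form in which `tau_k` is
#'   also the residual precision.
#' @return list with `mean` (length M), `precision` (M x M) and its upper
#'   Cholesky factor `chol`, class `beta_posterior`.
#' @export
compute_beta_posterior <- function(x, resp, weights, tau_k, zeta_k, eta,
                                   normal = FALSE) {
  x <- unclass(x)
  if (!all(is.finite(x)) || !all(is.finite(resp)) || !all(is.finite(weights)))
    stop("non-finite inputs to the coefficient posterior")
  stopifnot(length(resp) == nrow(x), length(weights) == nrow(x),
            all(weights > 0), tau_k > 0,
            length(zeta_k) == ncol(x), length(eta) == ncol(x))
  prior_diag <- zeta_k * eta
  if (normal) {
    xtx <- crossprod(x)
    a <- tau_k * (xtx + diag(prior_diag, ncol(x)))
    core <- xtx + diag(prior_diag, ncol(x))
    rhs <- crossprod(x, resp)
  } else {
    xw <- x * weights
    a <- crossprod(xw, x) + diag(tau_k * prior_diag, ncol(x))
    core <- a
    rhs <- crossprod(xw, resp)
  }
  ch_core <- chol_with_jitter(core)
  mean <- backsolve(ch_core, backsolve(ch_core, rhs, transpose = TRUE))
  ch_a <- if (normal) sqrt(tau_k) * ch_core else ch_core
  structure(list(mean = drop(mean), precision = a, chol = ch_a),
            class = "beta_posterior")
}

chol_with_jitter <- function(a) {
  ch <- tryCatch(chol(a), error = function(e) NULL)
  if (is.null(ch))
    ch <- chol(a + diag(1e-8, nrow(a)))
  ch
}

#' Draw a coefficient vector from its conditional posterior
#'
#' Samples `beta_k ~ MVN(m_k, A_k^{-1})` using the upper Cholesky factor R
#' of `A_k`: `beta = m_k + R^{-1} z`, `z ~ N(0, I)`.
#'
#' @param bp a `beta_posterior` from [compute_beta_posterior()].
#' @return numeric vector of length M.
#' @export
sample_beta <- function(bp) {
  stopifnot(inherits(bp, "beta_posterior"))
  z <- stats::rnorm(length(bp$mean))
  bp$mean + drop(backsolve(bp$chol, z))
}

#' Gibbs update of the shrinkage precisions
#'
#' Under the prior `beta_jk ~ N(0, 1/(tau_k zeta_jk eta_j))` with Jeffreys
#' hyperpriors `p(theta) ∝ 1/theta`, the full conditionals are Gamma
#' (shape-rate):
#' `tau_k ~ Gamma(M/2, 0.5 * sum_j zeta_jk eta_j beta_jk^2)`,
#' `eta_j ~ Gamma(K/2, 0.5 * sum_k tau_k zeta_jk beta_jk^2)`,
#' `zeta_jk ~ Gamma(1/2, 0.5 * tau_k eta_j beta_jk^2)`.
#' Draws are clipped to `[1e-12, 1e12]`; a rate of exactly zero (a whole
#' zero row/column of B) is floored at `1e-12`, which yields a diffuse
#' draw, with a warning.
#'
#' @param b M x K coefficient matrix.
#' @param state a [precision_state()].
#' @param tau_extra_shape,tau_extra_rate optional additions to the shape
#'   and rate of the `tau_k` conditional; the Normal model uses them to
#'   fold the Gaussian residual term into its shared residual/prior
#'   precision.
#' @return the updated [precision_state()].
#' @export
update_precisions <- function(b, state, tau_extra_shape = 0,
                              tau_extra_rate = 0) {
  b <- unclass(b)
  m <- nrow(b); k <- ncol(b)
  b2 <- b * b
  ze <- state$zeta * state$eta          # (M x K) * recycled length-M eta
  rate_tau <- 0.5 * colSums(ze * b2) + tau_extra_rate
  tau <- rgamma_clipped(k, shape = m / 2 + tau_extra_shape, rate = rate_tau)
  zt <- sweep(state$zeta, 2, tau, `*`)
  rate_eta <- 0.5 * rowSums(zt * b2)
  eta <- rgamma_clipped(m, shape = k / 2, rate = rate_eta)
  rate_zeta <- 0.5 * (outer(eta, tau) * b2)
  zeta <- matrix(rgamma_clipped(m * k, shape = 1 / 2, rate = rate_zeta),
                 m, k)
  precision_state(m, k, tau = tau, eta = eta, zeta = zeta)
}

rgamma_clipped <- function(n, shape, rate) {
  zero <- rate <= 0
  if (any(zero)) {
    warning("zero rate in a precision conditional; floored at 1e-12")
    rate[zero] <- 1e-12
  }
  pmin(pmax(stats::rgamma(n, shape = shape, rate = rate), 1e-12), 1e12)
}

#' Call associations from posterior coefficient draws
#'
#' Summarizes each coefficient by its posterior median and calls pair
#' (j, k) an association when the median exceeds `threshold_sd` robust
#' posterior standard deviations: `|median_jk| > threshold_sd * s_jk`,
#' where `s_jk = MAD(draws_jk) / 0.6745` is the per-coefficient robust SD
#' of its own retained draws. Under the Jeffreys shrinkage prior the
#' posterior of a null coefficient is crushed onto a spike at zero, so a
#' single scale pooled across coefficients would be degenerate (most
#' medians are numerically zero); the per-coefficient scale makes the rule
#' a posterior signal-to-noise test that is invariant to the many orders
#' of magnitude the shrinkage spans. A coefficient whose draws are all
#' identical (scale zero) is never called.
#'
#' @param beta_draws array of retained draws with dimensions
#'   (draws, M, K), or an `eqtl_fit`.
#' @param threshold_sd robust-SD multiplier (default 2.5).
#' @return M x K logical matrix of calls.
#' @export
call_associations <- function(beta_draws, threshold_sd = 2.5) {
  if (inherits(beta_draws, "eqtl_fit")) beta_draws <- beta_draws$beta_draws
  stopifnot(length(dim(beta_draws)) == 3, threshold_sd > 0)
  if (dim(beta_draws)[1] < 50)
    stop("need at least 50 retained draws to call associations")
  med <- apply(beta_draws, c(2, 3), stats::median)
  dev <- abs(sweep(beta_draws, c(2, 3), med))
  s <- apply(dev, c(2, 3), stats::median) / 0.6745
  s > 0 & abs(med) > threshold_sd * s
}
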