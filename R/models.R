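#' MCMC settings for the Gibbs samplers
#'
#' @param iterations total Gibbs sweeps (default 4000).
#' @param burnin sweeps discarded from the front (default 2000); retained
#'   draws number `iterations - burnin`.
#' @param seed integer root seed governing every random draw in a fit.
#' @param adapt_target target acceptance rate of the adaptive
#'   Metropolis-within-Gibbs steps (latent responses of the Poisson model,
#'   Negative Binomial dispersions); adaptation runs during burn-in only.
#' @return a list of class `mcmc_control`.
#' @export
mcmc_control <- function(iterations = 4000, burnin = 2000, seed = 1,
                         adapt_target = 0.4) {
  stopifnot(iterations > burnin, burnin >= 0, iterations >= 2,
            adapt_target > 0, adapt_target < 1)
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin),
                 seed = as.integer(seed),
                 adapt_target = adapt_target),
            class = "mcmc_control")
}

# Cholesky draw of beta_k: a = the system solved for the mean, rhs = X'W
# resp. The full precision is tau_scale * a (tau_scale = 1 except in the
# Normal model, whose shared tau multiplies X'X + prior jointly).
draw_beta_chol <- function(a, rhs, tau_scale = 1) {
  ch <- chol_with_jitter(a)
  mn <- drop(backsolve(ch, backsolve(ch, rhs, transpose = TRUE)))
  z <- stats::rnorm(length(mn)) / sqrt(tau_scale)
  list(mean = mn, draw = mn + drop(backsolve(ch, z)))
}

new_eqtl_fit <- function(model, beta_draws, mu_draws, x, transform,
                         marker_ids, transcript_ids, control, extra = list()) {
  structure(c(list(
    model = model,
    beta_draws = beta_draws,
    mu_draws = mu_draws,
    x_center = attr(x, "scaled:center"),
    transform = transform,
    marker_ids = marker_ids,
    transcript_ids = transcript_ids,
    mcmc = list(iterations = control$iterations, burnin = control$burnin,
                seed = control$seed),
    filters = NULL), extra),
    class = "eqtl_fit")
}

#' Posterior-median coefficient matrix of a fit
#'
#' @param fit an `eqtl_fit`.
#' @return M x K matrix of posterior medians of the regression coefficients.
#' @export
coef_median <- function(fit) {
  stopifnot(inherits(fit, "eqtl_fit"))
  out <- apply(fit$beta_draws, c(2, 3), stats::median)
  dimnames(out) <- list(fit$marker_ids, fit$transcript_ids)
  out
}

resolve_offset <- function(offset, z) {
  if (is.null(offset))
    return(log(size_factors(z, "median_of_ratios")))
  if (identical(offset, "none")) return(rep(0, nrow(z)))
  stopifnot(is.numeric(offset), length(offset) == nrow(z),
            all(is.finite(offset)))
  offset
}

check_xy <- function(x, yz) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (nrow(x) != nrow(yz))
    stop("genotype and expression matrices must have the same samples")
  if (ncol(x) == 0 || ncol(yz) == 0)
    stop("need at least one marker and one transcript")
}

#' Fit the Normal model on transformed expression
#'
#' Gibbs sampler for `y_ik ~ N(mu_k + x_i' beta_k, 1 / tau_k)` under the
#' three-level shrinkage prior, where `tau_k` is shared between the
#' residual precision and the prior scale. Genotype columns are
#' mean-centered and each transcript carries its own intercept, so the
#' zero-centered prior is coherent. Per sweep: draw each `beta_k` from its
#' closed-form multivariate-Normal conditional, the intercepts from their
#' conjugate Normal conditionals, and the precisions (`tau` with the
#' residual term folded in, then `eta`, `zeta`) from their Gamma
#' conditionals.
#'
#' @param x a [genotype_matrix()].
#' @param y a [transformed_matrix()] (or numeric matrix) of expression.
#' @param control an [mcmc_control()].
#' @return an `eqtl_fit` with retained draws of B and the intercepts.
#' @export
fit_normal <- function(x, y, control = mcmc_control()) {
  check_xy(x, y)
  set.seed(control$seed)
  transform <- if (inherits(y, "transformed_matrix")) attr(y, "method") else "none"
  yv <- raw_values(y)
  xc <- scale(raw_values(x), center = TRUE, scale = FALSE)
  n <- nrow(xc); m <- ncol(xc); k <- ncol(yv)
  xtx <- crossprod(xc)
  state <- precision_state(m, k)
  beta <- matrix(0, m, k)
  mu <- colMeans(yv)
  s <- control$iterations - control$burnin
  beta_draws <- array(NA_real_, c(s, m, k))
  mu_draws <- matrix(NA_real_, s, k)
  tau_draws <- matrix(NA_real_, s, k)
  for (it in seq_len(control$iterations)) {
    resid0 <- sweep(yv, 2, mu)        # y - mu
    rhs_all <- crossprod(xc, resid0)  # M x K
    for (j in seq_len(k)) {
      core <- xtx + diag(state$zeta[, j] * state$eta, m)
      beta[, j] <- draw_beta_chol(core, rhs_all[, j],
                                  tau_scale = state$tau[j])$draw
    }
    fitted <- xc %*% beta
    # conjugate intercepts: mu_k ~ N(mean residual, 1 / (N tau_k))
    mu <- colMeans(yv - fitted) +
      stats::rnorm(k, 0, sqrt(1 / (n * state$tau)))
    rss <- colSums((yv - fitted - rep(mu, each = n))^2)
    state <- update_precisions(beta, state,
                               tau_extra_shape = n / 2,
                               tau_extra_rate = rss / 2)
    if (it > control$burnin) {
      idx <- it - control$burnin
      beta_draws[idx, , ] <- beta
      mu_draws[idx, ] <- mu
      tau_draws[idx, ] <- state$tau
    }
  }
  new_eqtl_fit("normal", beta_draws, mu_draws, xc, transform,
               colnames(x), colnames(yv), control,
               extra = list(tau_draws = tau_draws))
}

# shared beta/mu/sigma2 block for the latent-Normal count models
# (Poisson and Binomial): given latent y, the model is y_ik ~
# N(mu_k + x beta_k, sigma2_k) with the shrinkage prior on beta.
draw_latent_normal_block <- function(xc, xtx, y, mu, sigma2, state) {
  n <- nrow(xc); m <- ncol(xc); k <- ncol(y)
  beta <- matrix(0, m, k)
  rhs_all <- crossprod(xc, sweep(y, 2, mu))
  for (j in seq_len(k)) {
    a <- xtx / sigma2[j] +
      diag(state$tau[j] * state$zeta[, j] * state$eta, m)
    beta[, j] <- draw_beta_chol(a, rhs_all[, j] / sigma2[j])$draw
  }
  fitted <- xc %*% beta
  mu <- colMeans(y - fitted) + stats::rnorm(k, 0, sqrt(sigma2 / n))
  rss <- colSums((y - fitted - rep(mu, each = n))^2)
  # conjugate inverse-Gamma(1, 1) prior on sigma2_k
  sigma2 <- 1 / stats::rgamma(k, shape = 1 + n / 2, rate = 1 + rss / 2)
  list(beta = beta, mu = mu, sigma2 = sigma2, fitted = fitted)
}

#' Fit the over-dispersed Poisson (Poisson-LogNormal) model
#'
#' Counts follow `z_ik ~ Poisson(exp(y_ik + o_i))` with log size-factor
#' offsets `o_i`, and the latent log-rates are Normal,
#' `y_ik ~ N(mu_k + x_i' beta_k, sigma_k^2)` — a Poisson-LogNormal
#' mixture whose latent variance `sigma_k^2` carries the over-dispersion.
#' The latent responses have no conjugate update and use per-entry
#' adaptive random-walk Metropolis (tuned towards the target acceptance
#' rate during burn-in); given the latents, the coefficient, intercept and
#' variance updates are the conjugate Normal-model ones, followed by the
#' shrinkage-precision updates.
#'
#' @param x a [genotype_matrix()].
#' @param z a [count_matrix()].
#' @param control an [mcmc_control()].
#' @param offset per-sample log offsets absorbing sequencing depth:
#'   `NULL` (default) uses log median-of-ratios size factors (robust to
#'   composition effects, where a few strongly genotype-driven transcripts
#'   dominate the library), `"none"` uses zero offsets, or a length-N
#'   numeric vector of known log depths.
#' @return an `eqtl_fit`; `accept_rate` holds per-transcript post-burn-in
#'   Metropolis acceptance rates of the latent updates.
#' @export
fit_poisson <- function(x, z, control = mcmc_control(), offset = NULL) {
  check_xy(x, z)
  set.seed(control$seed)
  zv <- raw_values(z)
  if (any(colSums(zv) == 0))
    warning("all-zero transcript(s); the intercept will absorb them")
  xc <- scale(raw_values(x), center = TRUE, scale = FALSE)
  n <- nrow(xc); m <- ncol(xc); k <- ncol(zv)
  xtx <- crossprod(xc)
  offset <- resolve_offset(offset, z)
  state <- precision_state(m, k)
  y <- log(zv + 0.5) - offset
  mu <- colMeans(y)
  sigma2 <- rep(1, k)
  beta <- matrix(0, m, k)
  fitted <- matrix(0, n, k)
  step <- matrix(0.5, n, k)          # adaptive RW scales, burn-in only
  acc_post <- matrix(0, n, k)
  s <- control$iterations - control$burnin
  beta_draws <- array(NA_real_, c(s, m, k))
  mu_draws <- matrix(NA_real_, s, k)
  sigma2_draws <- matrix(NA_real_, s, k)
  for (it in seq_len(control$iterations)) {
    # (i) Metropolis update of the latent log-rates
    prior_mean <- sweep(fitted, 2, mu, `+`)
    prop <- y + step * matrix(stats::rnorm(n * k), n, k)
    log_acc <- zv * (prop - y) - exp(offset) * (exp(prop) - exp(y)) -
      ((prop - prior_mean)^2 - (y - prior_mean)^2) /
        (2 * rep(sigma2, each = n))
    acc <- log(matrix(stats::runif(n * k), n, k)) < log_acc
    y[acc] <- prop[acc]
    if (it <= control$burnin) {
      step <- step * exp(it^-0.55 * ((acc + 0) - control$adapt_target))
    } else {
      acc_post <- acc_post + acc
    }
    # (ii) conjugate block given the latents, (iii) shrinkage precisions
    blk <- draw_latent_normal_block(xc, xtx, y, mu, sigma2, state)
    beta <- blk$beta; mu <- blk$mu; sigma2 <- blk$sigma2
    fitted <- blk$fitted
    state <- update_precisions(beta, state)
    if (it > control$burnin) {
      idx <- it - control$burnin
      beta_draws[idx, , ] <- beta
      mu_draws[idx, ] <- mu
      sigma2_draws[idx, ] <- sigma2
    }
  }
  new_eqtl_fit("pois", beta_draws, mu_draws, xc, "none",
               colnames(x), colnames(zv), control,
               extra = list(sigma2_draws = sigma2_draws, offset = offset,
                            accept_rate = colMeans(acc_post / s)))
}

#' Fit the over-dispersed Binomial model
#'
#' Counts follow `z_ik ~ Binomial(n_i, sigmoid(y_ik))` with `n_i` the
#' library size of sample i, and logit-Normal mixing
#' `y_ik ~ N(mu_k + x_i' beta_k, sigma_k^2)` carries the
#' over-dispersion. Polya-Gamma augmentation (`omega_ik ~ PG(n_i, y_ik)`)
#' makes each latent `y_ik` conditionally Normal, so the whole sweep is
#' Gibbs: draw omega, draw the latents in closed form, then the conjugate
#' coefficient/intercept/variance block and the shrinkage precisions.
#'
#' @inheritParams fit_poisson
#' @param lib_sizes per-sample Binomial denominators; default (`NULL`) uses
#'   the observed library sizes (row sums of `z`).
#' @return an `eqtl_fit`.
#' @export
fit_binomial <- function(x, z, control = mcmc_control(), lib_sizes = NULL) {
  check_xy(x, z)
  set.seed(control$seed)
  zv <- raw_values(z)
  lib <- if (is.null(lib_sizes)) rowSums(zv) else lib_sizes
  stopifnot(length(lib) == nrow(zv))
  if (any(lib <= 0)) stop("every sample needs a positive library size")
  if (any(zv > lib)) stop("counts cannot exceed library sizes")
  xc <- scale(raw_values(x), center = TRUE, scale = FALSE)
  n <- nrow(xc); m <- ncol(xc); k <- ncol(zv)
  xtx <- crossprod(xc)
  state <- precision_state(m, k)
  p0 <- (zv + 0.5) / (lib + 1)
  y <- log(p0 / (1 - p0))
  mu <- colMeans(y)
  sigma2 <- rep(1, k)
  fitted <- matrix(0, n, k)
  kappa <- zv - lib / 2
  s <- control$iterations - control$burnin
  beta_draws <- array(NA_real_, c(s, m, k))
  mu_draws <- matrix(NA_real_, s, k)
  sigma2_draws <- matrix(NA_real_, s, k)
  for (it in seq_len(control$iterations)) {
    omega <- matrix(rpolyagamma(n * k, b = rep(lib, k), c = as.vector(y)),
                    n, k)
    # latent y | omega is Normal: precision omega + 1/sigma2
    prior_mean <- sweep(fitted, 2, mu, `+`)
    prec <- omega + 1 / rep(sigma2, each = n)
    mean_y <- (kappa + prior_mean / rep(sigma2, each = n)) / prec
    y <- mean_y + matrix(stats::rnorm(n * k), n, k) / sqrt(prec)
    blk <- draw_latent_normal_block(xc, xtx, y, mu, sigma2, state)
    mu <- blk$mu; sigma2 <- blk$sigma2; fitted <- blk$fitted
    state <- update_precisions(blk$beta, state)
    if (it > control$burnin) {
      idx <- it - control$burnin
      beta_draws[idx, , ] <- blk$beta
      mu_draws[idx, ] <- mu
      sigma2_draws[idx, ] <- sigma2
    }
  }
  new_eqtl_fit("bin", beta_draws, mu_draws, xc, "none",
               colnames(x), colnames(zv), control,
               extra = list(sigma2_draws = sigma2_draws, lib_sizes = lib))
}

# Negative Binomial log-likelihood of one transcript in the log-odds
# parameterization: z ~ NB(r, p), p = sigmoid(psi), mean = r exp(psi)
nb_loglik <- function(z, r, psi) {
  softplus <- ifelse(psi > 0, psi + log1p(exp(-psi)), log1p(exp(psi)))
  sum(lgamma(z + r)) - length(z) * lgamma(r) +
    sum(z * psi - (z + r) * softplus)
}

#' Fit the Negative Binomial model
#'
#' Counts follow `z_ik ~ NB(r_k, p_ik)` with success probability
#' `p_ik = sigmoid(psi_ik)` and log-odds
#' `psi_ik = mu_k + o_i + x_i' beta_k` (`o_i` the log size factor), so the
#' conditional mean is `r_k exp(psi_ik)`. Polya-Gamma auxiliaries
#' `omega_ik ~ PG(z_ik + r_k, psi_ik)` turn the NB likelihood into a
#' Gaussian one in `psi`, giving the closed-form multivariate-Normal
#' conditional for each `beta_k` with weights omega and pseudo-data
#' `(z_ik - r_k) / (2 omega_ik)`. The dispersions `r_k` are updated by
#' adaptive random-walk Metropolis on `log r_k` under a weakly informative
#' Gamma(2, 0.1) prior (which keeps the posterior proper on near-Poisson
#' transcripts).
#'
#' @inheritParams fit_poisson
#' @return an `eqtl_fit`; `r_draws` holds dispersion draws and
#'   `accept_rate` the per-transcript dispersion acceptance rates.
#' @export
fit_nbin <- function(x, z, control = mcmc_control(), offset = NULL) {
  check_xy(x, z)
  set.seed(control$seed)
  zv <- raw_values(z)
  xc <- scale(raw_values(x), center = TRUE, scale = FALSE)
  n <- nrow(xc); m <- ncol(xc); k <- ncol(zv)
  offset <- resolve_offset(offset, z)
  state <- precision_state(m, k)
  # moment-based dispersion inits, clipped to a sane range
  mns <- colMeans(zv); vars <- apply(zv, 2, stats::var)
  r <- pmin(pmax(mns^2 / pmax(vars - mns, 1e-8), 0.1), 100)
  mu <- log(pmax(mns, 0.5)) - log(r)
  beta <- matrix(0, m, k)
  fitted <- matrix(0, n, k)
  step_r <- rep(0.3, k)
  acc_post <- numeric(k)
  s <- control$iterations - control$burnin
  beta_draws <- array(NA_real_, c(s, m, k))
  mu_draws <- matrix(NA_real_, s, k)
  r_draws <- matrix(NA_real_, s, k)
  for (it in seq_len(control$iterations)) {
    psi <- sweep(fitted, 2, mu, `+`) + offset
    omega <- matrix(
      rpolyagamma(n * k, b = as.vector(zv) + rep(r, each = n),
                  c = as.vector(psi)), n, k)
    # beta_k | omega: weighted Gaussian regression on the PG pseudo-data
    pseudo <- (zv - rep(r, each = n)) / (2 * omega)
    for (j in seq_len(k)) {
      w <- omega[, j]
      resp <- pseudo[, j] - mu[j] - offset
      xw <- xc * w
      a <- crossprod(xw, xc) +
        diag(state$tau[j] * state$zeta[, j] * state$eta, m)
      beta[, j] <- draw_beta_chol(a, crossprod(xw, resp))$draw
    }
    fitted <- xc %*% beta
    # conjugate intercepts under the same augmentation
    resid_mu <- pseudo - fitted - offset
    wsum <- colSums(omega)
    mu <- colSums(omega * resid_mu) / wsum +
      stats::rnorm(k, 0, sqrt(1 / wsum))
    # dispersion: random-walk Metropolis on log r_k. A weakly informative
    # Gamma(2, 0.1) prior keeps the posterior proper: the NB likelihood is
    # flat along the Poisson limit (r -> Inf with the intercept
    # compensating), so a flat prior on log r would let r drift without
    # bound on near-Poisson transcripts.
    psi <- sweep(fitted, 2, mu, `+`) + offset
    r_prop <- r * exp(step_r * stats::rnorm(k))
    for (j in seq_len(k)) {
      la <- nb_loglik(zv[, j], r_prop[j], psi[, j]) -
        nb_loglik(zv[, j], r[j], psi[, j]) +
        stats::dgamma(r_prop[j], 2, rate = 0.1, log = TRUE) -
        stats::dgamma(r[j], 2, rate = 0.1, log = TRUE) +
        log(r_prop[j]) - log(r[j])   # Jacobian of the log-scale walk
      if (log(stats::runif(1)) < la) {
        r[j] <- r_prop[j]
        if (it > control$burnin) acc_post[j] <- acc_post[j] + 1
        if (it <= control$burnin)
          step_r[j] <- step_r[j] * exp(it^-0.55 * (1 - control$adapt_target))
      } else if (it <= control$burnin) {
        step_r[j] <- step_r[j] * exp(-it^-0.55 * control$adapt_target)
      }
    }
    state <- update_precisions(beta, state)
    if (it > control$burnin) {
      idx <- it - control$burnin
      beta_draws[idx, , ] <- beta
      mu_draws[idx, ] <- mu
      r_draws[idx, ] <- r
    }
  }
  new_eqtl_fit("nbin", beta_draws, mu_draws, xc, "none",
               colnames(x), colnames(zv), control,
               extra = list(r_draws = r_draws, offset = offset,
                            accept_rate = acc_post / s))
}

#' Predict expression for new genotypes
#'
#' Plugs posterior-median parameters into the model mean: Normal
#' `mu_k + x' beta`, Poisson `exp(mu_k + o + x' beta + sigma_k^2 / 2)`
#' (the log-Normal mean correction), Binomial `n * sigmoid(mu_k + x' beta)`
#' and Negative Binomial `r_k exp(mu_k + o + x' beta)`.
#'
#' @param fit an `eqtl_fit`.
#' @param x_new a [genotype_matrix()] with the markers of the fit.
#' @param offset per-sample log size-factor offsets for the Poisson /
#'   Negative Binomial models (default 0 = average depth).
#' @param lib_sizes per-sample library sizes for the Binomial model
#'   (default: mean training library size).
#' @return numeric matrix (samples x transcripts) on the transformed scale
#'   (Normal) or the expected-count scale (count models).
#' @export
predict_expression <- function(fit, x_new, offset = NULL, lib_sizes = NULL) {
  stopifnot(inherits(fit, "eqtl_fit"))
  if (!identical(colnames(x_new), fit$marker_ids))
    stop("markers of x_new do not match the fitted markers")
  xc <- sweep(raw_values(x_new), 2, fit$x_center)
  bhat <- apply(fit$beta_draws, c(2, 3), stats::median)
  muhat <- apply(fit$mu_draws, 2, stats::median)
  lin <- sweep(xc %*% bhat, 2, muhat, `+`)
  n <- nrow(xc)
  if (is.null(offset)) offset <- rep(0, n)
  out <- switch(fit$model,
    normal = lin,
    pois = {
      s2 <- apply(fit$sigma2_draws, 2, stats::median)
      exp(lin + offset + rep(s2 / 2, each = n))
    },
    bin = {
      if (is.null(lib_sizes)) lib_sizes <- rep(mean(fit$lib_sizes), n)
      lib_sizes * stats::plogis(lin)
    },
    nbin = {
      rhat <- apply(fit$r_draws, 2, stats::median)
      rep(rhat, each = n) * exp(lin + offset)
    },
    stop("unknown model: ", fit$model))
  dimnames(out) <- list(rownames(x_new), fit$transcript_ids)
  out
}

#' @export
print.eqtl_fit <- function(x, ...) {
  s <- dim(x$beta_draws)[1]
  cat(sprintf("<eqtl_fit: %s model%s, %d markers x %d transcripts>\n",
              x$model,
              if (x$transform != "none") paste0(" (", x$transform, ")") else "",
              length(x$marker_ids), length(x$transcript_ids)))
  cat(sprintf("  %d retained draws (%d sweeps, %d burn-in), seed %d\n",
              s, x$mcmc$iterations, x$mcmc$burnin, x$mcmc$seed))
  cat(sprintf("  associations called at 2.5 robust SDs: %d\n",
              sum(call_associations(x$beta_draws))))
  invisible(x)
}
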