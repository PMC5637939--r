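ctl_short <- function(seed) mcmc_control(600, 300, seed = seed)

test_that("fits are exactly reproducible given inputs, seed and settings", {
  sim <- selfsim_normal(n = 80, m = 4, k = 5, n_effects = 2, seed = 3)
  f1 <- fit_normal(sim$x, sim$y, ctl_short(9))
  f2 <- fit_normal(sim$x, sim$y, ctl_short(9))
  expect_identical(f1$beta_draws, f2$beta_draws)
  zp <- selfsim_pois(n = 60, m = 4, k = 5, n_effects = 2, seed = 3)
  p1 <- fit_poisson(zp$x, zp$z, ctl_short(9), offset = zp$offset)
  p2 <- fit_poisson(zp$x, zp$z, ctl_short(9), offset = zp$offset)
  expect_identical(p1$beta_draws, p2$beta_draws)
  n1 <- fit_nbin(zp$x, zp$z, ctl_short(9))
  n2 <- fit_nbin(zp$x, zp$z, ctl_short(9))
  expect_identical(n1$beta_draws, n2$beta_draws)
  b1 <- fit_binomial(zp$x, zp$z, ctl_short(9))
  b2 <- fit_binomial(zp$x, zp$z, ctl_short(9))
  expect_identical(b1$beta_draws, b2$beta_draws)
})

test_that("retained draw count and dimensions follow the MCMC settings", {
  sim <- selfsim_normal(n = 60, m = 3, k = 4, n_effects = 1, seed = 5)
  fit <- fit_normal(sim$x, sim$y, mcmc_control(250, 100, seed = 1))
  expect_equal(dim(fit$beta_draws), c(150L, 3L, 4L))
  expect_equal(dim(fit$mu_draws), c(150L, 4L))
  expect_error(mcmc_control(100, 100), "iterations")
})

test_that("permuting sample order leaves posterior medians unchanged up to MC error", {
  sim <- selfsim_normal(n = 200, m = 5, k = 6, n_effects = 3, seed = 7)
  f1 <- fit_normal(sim$x, sim$y, mcmc_control(800, 400, seed = 4))
  set.seed(77)
  perm <- sample(nrow(sim$x))
  xp <- genotype_matrix(unclass(sim$x)[perm, ], rownames(sim$x)[perm],
                        colnames(sim$x))
  yp <- transformed_matrix(unclass(sim$y)[perm, ])
  f2 <- fit_normal(xp, yp, mcmc_control(800, 400, seed = 5))
  expect_lt(max(abs(coef_median(f1) - coef_median(f2))), 0.06)
})

test_that("the Poisson sampler adapts its latent acceptance into the target band", {
  zp <- selfsim_pois(n = 100, m = 4, k = 6, n_effects = 2, seed = 8)
  fit <- fit_poisson(zp$x, zp$z, mcmc_control(800, 400, seed = 3),
                     offset = zp$offset)
  expect_true(all(fit$accept_rate > 0.2 & fit$accept_rate < 0.6))
})

test_that("pois matches the Normal model on log counts in the large-count limit", {
  # dense moderate effects and means ~1000 so the Poisson noise is
  # negligible relative to the latent Normal variation
  set.seed(14)
  n <- 200; m <- 4; k <- 6
  x <- genotype_matrix(matrix(rbinom(n * m, 2, 0.4), n, m))
  xc <- scale(unclass(x), scale = FALSE)
  b <- matrix(rnorm(m * k, 0, 0.25), m, k)
  lat <- sweep(xc %*% b, 2, log(1000), `+`) + matrix(rnorm(n * k, 0, 0.2), n, k)
  z <- count_matrix(matrix(rpois(n * k, exp(as.vector(lat))), n, k))
  fp <- fit_poisson(x, z, mcmc_control(800, 400, seed = 5), offset = "none")
  fn <- fit_normal(x, log_transform(z), mcmc_control(800, 400, seed = 6))
  expect_gt(cor(as.vector(coef_median(fp)), as.vector(coef_median(fn)),
                method = "spearman"), 0.9)
})

test_that("nbin approaches pois when the dispersion is large", {
  set.seed(15)
  n <- 200; m <- 4; k <- 6
  x <- genotype_matrix(matrix(rbinom(n * m, 2, 0.4), n, m))
  xc <- scale(unclass(x), scale = FALSE)
  b <- matrix(rnorm(m * k, 0, 0.25), m, k)
  lat <- sweep(xc %*% b, 2, log(300), `+`)
  z <- count_matrix(matrix(rpois(n * k, exp(as.vector(lat))), n, k))
  fnb <- fit_nbin(x, z, mcmc_control(800, 400, seed = 7), offset = "none")
  fp <- fit_poisson(x, z, mcmc_control(800, 400, seed = 8), offset = "none")
  expect_gt(cor(as.vector(coef_median(fnb)), as.vector(coef_median(fp)),
                method = "spearman"), 0.9)
})

test_that("a symmetric Binomial null centers the latent scale and calls nothing", {
  set.seed(16)
  n <- 80
  lib <- rep(400L, n)
  z <- count_matrix(cbind(g1 = rep(200L, n), g2 = rep(200L, n)))
  x <- genotype_matrix(matrix(rbinom(n * 3, 2, 0.3), n, 3))
  fit <- fit_binomial(x, z, mcmc_control(600, 300, seed = 2))
  # logit(1/2) = 0: posterior intercepts straddle zero
  expect_lt(max(abs(apply(fit$mu_draws, 2, median))), 0.05)
  expect_false(any(call_associations(fit)))
})

test_that("binomial fits are invariant to doubling libraries and counts together", {
  zb <- selfsim_bin(n = 150, m = 4, k = 6, n_effects = 2, seed = 9)
  f1 <- fit_binomial(zb$x, zb$z, mcmc_control(800, 400, seed = 3))
  z2 <- count_matrix(2L * unclass(zb$z))
  f2 <- fit_binomial(zb$x, z2, mcmc_control(800, 400, seed = 4))
  expect_lt(max(abs(coef_median(f1) - coef_median(f2))), 0.1)
})

test_that("all-zero transcripts are tolerated with a warning", {
  zp <- selfsim_pois(n = 50, m = 3, k = 4, n_effects = 0, seed = 10)
  zz <- unclass(zp$z); zz[, 2] <- 0L
  expect_warning(fit_poisson(zp$x, count_matrix(zz),
                             mcmc_control(200, 100, seed = 1)),
                 "all-zero")
})

test_that("prediction interpolates a noiseless Normal fit and respects B = 0", {
  sim <- selfsim_normal(n = 150, m = 5, k = 5, n_effects = 5,
                        sigma = 0.02, seed = 11)
  fit <- fit_normal(sim$x, sim$y, mcmc_control(600, 300, seed = 2))
  pred <- predict_expression(fit, sim$x)
  ss_res <- sum((pred - unclass(sim$y))^2)
  ss_tot <- sum(scale(unclass(sim$y), scale = FALSE)^2)
  expect_gt(1 - ss_res / ss_tot, 0.99)
  # a fit with no effects predicts a constant per transcript
  sim0 <- selfsim_normal(n = 100, m = 4, k = 3, n_effects = 0, seed = 12)
  fit0 <- fit_normal(sim0$x, sim0$y, mcmc_control(400, 200, seed = 3))
  pred0 <- predict_expression(fit0, sim0$x)
  expect_lt(max(apply(pred0, 2, function(cl) diff(range(cl)))), 1e-3)
  # marker mismatch is an error
  xbad <- genotype_matrix(unclass(sim$x),
                          rownames(sim$x), paste0("other", 1:5))
  expect_error(predict_expression(fit, xbad), "markers")
})

test_that("tidy/glance/autoplot expose the fit as tables and figures", {
  sim <- selfsim_normal(n = 80, m = 3, k = 4, n_effects = 1, seed = 6)
  fit <- fit_normal(sim$x, sim$y, mcmc_control(300, 150, seed = 1))
  tab <- tidy(fit)
  expect_s3_class(tab, "tbl_df")
  expect_equal(nrow(tab), 12L)
  expect_true(all(c("marker_id", "transcript_id", "beta_median",
                    "beta_lo", "beta_hi", "called") %in% names(tab)))
  gl <- glance(fit)
  expect_equal(gl$n_markers, 3L)
  expect_equal(gl$model, "normal")
  expect_s3_class(autoplot(fit), "ggplot")
})
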