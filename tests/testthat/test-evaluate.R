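test_that("MCC matches hand-built confusion matrices and the phi-coefficient oracle", {
  # perfect and inverted classifiers
  tr <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  expect_equal(mcc(tr, tr), 1)
  expect_equal(mcc(!tr, tr), -1)
  # TP=4 FP=1 FN=1 TN=14 -> (4*14 - 1) / sqrt(5*5*15*15) = 55/75
  called <- c(rep(TRUE, 5), rep(FALSE, 15))
  truth <- c(rep(TRUE, 4), FALSE, TRUE, rep(FALSE, 14))
  expect_equal(mcc(called, truth), 55 / 75)
  # MCC is the Pearson correlation of the binary indicators
  set.seed(1)
  for (i in 1:100) {
    a <- runif(40) < runif(1, 0.2, 0.8)
    b <- runif(40) < runif(1, 0.2, 0.8)
    expected <- suppressWarnings(cor(as.numeric(a), as.numeric(b)))
    if (is.na(expected)) expected <- 0
    expect_equal(mcc(a, b), expected, tolerance = 1e-12)
  }
  # symmetry under joint class-label swap
  set.seed(2)
  a <- runif(50) < 0.3; b <- runif(50) < 0.3
  expect_equal(mcc(a, b), mcc(!a, !b))
})

test_that("degenerate confusion tables give MCC 0", {
  expect_equal(mcc(rep(TRUE, 4), c(TRUE, TRUE, FALSE, FALSE)), 0)
  expect_equal(mcc(rep(FALSE, 4), rep(FALSE, 4)), 0)
})

test_that("CCC matches the textbook formula and is bounded by Pearson", {
  expect_equal(ccc(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_equal(ccc(c(1, -2, 3, -2), -c(1, -2, 3, -2)), -1)
  expect_equal(ccc(c(1, 2, 3, 4), c(1.5, 2, 3, 3.5)), 0.9333333,
               tolerance = 1e-6)
  set.seed(3)
  for (i in 1:100) {
    a <- rnorm(30); b <- 0.5 * a + rnorm(30, sd = runif(1, 0.1, 2))
    n <- length(a)
    va <- var(a) * (n - 1) / n; vb <- var(b) * (n - 1) / n
    expected <- 2 * cor(a, b) * sqrt(va) * sqrt(vb) /
      (va + vb + (mean(a) - mean(b))^2)
    expect_equal(ccc(a, b), expected, tolerance = 1e-12)
    expect_lte(abs(ccc(a, b)), abs(cor(a, b)) + 1e-12)
  }
  # equality with Pearson iff means and variances agree
  a <- rnorm(50); b <- a[sample(50)]
  expect_equal(abs(ccc(a, b)), abs(cor(a, b) *
    2 * sqrt(var(a) * var(b)) / (var(a) + var(b))), tolerance = 1e-12)
  expect_warning(v <- ccc(rep(1, 5), rep(2, 5)), "constant")
  expect_equal(v, 0)
})

test_that("effect-size RMSE is scale-free and restricted to true positives", {
  b <- matrix(c(1, 0, 0, -2), 2, 2)
  called <- b != 0
  expect_equal(rmse_true_positives(b, b, called, b != 0), 0)
  expect_equal(rmse_true_positives(2 * b, b, called, b != 0), 0)
  # one true positive with a known discrepancy after max-abs scaling:
  # est (1, 0.5) scaled by 1; truth (1, 1) scaled by 1 -> only TP (2,2)
  best <- matrix(c(1, 0, 0, 0.5), 2, 2)
  btr <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(rmse_true_positives(best, btr, matrix(c(FALSE, FALSE, FALSE,
                                                       TRUE), 2, 2),
                                   btr != 0), 0.5)
  expect_true(is.na(rmse_true_positives(b, b, !called, b != 0)))
})

test_that("benchmark_fit summarizes a fit against the planted truth", {
  sim <- selfsim_normal(n = 150, m = 5, k = 8, n_effects = 3, seed = 4)
  fit <- fit_normal(sim$x, sim$y, mcmc_control(500, 250, seed = 1))
  bench <- benchmark_fit(fit, structure(list(
    b_true = sim$b, hotspot_markers = integer(0),
    polygenic_transcripts = integer(0),
    config = simulation_config(n = 150, m = 5, k = 8, seed = 1)),
    class = "simulation_truth"))
  expect_equal(bench$n_tp + bench$n_fp + bench$n_fn + bench$n_tn, 40L)
  expect_gte(bench$mcc, 0.8)
  expect_equal(bench$tpr, 1)
})

test_that("Monte Carlo cross-validation is reproducible and self-consistent", {
  sim <- selfsim_normal(n = 120, m = 4, k = 8, n_effects = 4,
                        sigma = 0.05, seed = 5)
  # feed the generating transformed matrix through a count-free path:
  # build counts whose arcsin transform is irrelevant here, so use the
  # Normal model on log counts generated noiselessly from a Poisson fit
  zp <- selfsim_pois(n = 120, m = 4, k = 8, n_effects = 4, sigma = 0.1,
                     depth_sd = 0, seed = 5)
  cv1 <- monte_carlo_cv(zp$x, zp$z, model = "log", repeats = 2, seed = 9,
                        control = mcmc_control(500, 250))
  cv2 <- monte_carlo_cv(zp$x, zp$z, model = "log", repeats = 2, seed = 9,
                        control = mcmc_control(500, 250))
  expect_identical(cv1$results, cv2$results)
  expect_gt(cv1$mean_ccc, 0.9)
  expect_s3_class(tidy(cv1), "tbl_df")
  expect_equal(nrow(tidy(cv1)), 2L)
  expect_equal(glance(cv1)$repeats, 2L)
})

test_that("shuffling transcript labels destroys predictive concordance", {
  zp <- selfsim_pois(n = 120, m = 4, k = 8, n_effects = 6, sigma = 0.1,
                     depth_sd = 0, seed = 6)
  cv_good <- monte_carlo_cv(zp$x, zp$z, model = "log", repeats = 2,
                            seed = 3, control = mcmc_control(500, 250))
  set.seed(8)
  zshuf <- unclass(zp$z)[sample(nrow(zp$z)), ]
  cv_bad <- monte_carlo_cv(zp$x, count_matrix(zshuf), model = "log",
                           repeats = 2, seed = 3,
                           control = mcmc_control(500, 250))
  expect_gt(mean(tidy(cv_good)$n_called, na.rm = TRUE),
            mean(tidy(cv_bad)$n_called, na.rm = TRUE) - 0.5)
  expect_gte(cv_good$mean_ccc, cv_bad$mean_ccc - 0.02)
})
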