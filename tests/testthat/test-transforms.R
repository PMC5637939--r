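test_that("size factors match hand-computed cases", {
  z <- count_matrix(rbind(c(10, 20, 5), c(10, 20, 5)))
  expect_equal(unname(size_factors(z, "total_count")), c(1, 1))
  expect_equal(unname(size_factors(z, "median_of_ratios")), c(1, 1))
  # sample 2 at twice the depth of sample 1: total-count factors 2/3, 4/3
  z2 <- count_matrix(rbind(c(10, 20, 5), c(20, 40, 10)))
  expect_equal(unname(size_factors(z2, "total_count")), c(2 / 3, 4 / 3))
  expect_equal(unname(size_factors(z2, "median_of_ratios")),
               c(1 / sqrt(2), sqrt(2)))
  z1 <- count_matrix(matrix(c(3, 8, 1), 1, 3))
  expect_equal(unname(size_factors(z1, "total_count")), 1)
  # no all-positive transcript: fall back with a warning
  z0 <- count_matrix(rbind(c(0, 5), c(5, 0)))
  expect_warning(sf <- size_factors(z0, "median_of_ratios"), "falling back")
  expect_equal(unname(sf), c(1, 1))
})

test_that("Laplace smoothing follows the additive-smoothing formula", {
  z <- count_matrix(rbind(c(0, 9), c(5, 5)))
  p <- laplace_smooth(z, c = 1)
  expect_equal(unname(p[1, ]), c(1 / 11, 10 / 11))
  expect_equal(unname(p[2, ]), c(0.5, 0.5))
  expect_error(laplace_smooth(z, c = 0), "positive")
  expect_error(laplace_smooth(z, c = -2), "positive")
  # an all-zero row degenerates to the uniform distribution
  zz <- count_matrix(rbind(c(0, 0, 0), c(1, 2, 3)))
  expect_equal(unname(laplace_smooth(zz, 1)[1, ]), rep(1 / 3, 3))
})

test_that("smoothed rows sum to 1 and entries sit between empirical and uniform", {
  set.seed(9)
  for (i in 1:5) {
    z <- count_matrix(matrix(rpois(60, 20), 6, 10))
    p <- laplace_smooth(z, c = 1)
    expect_true(all(abs(rowSums(p) - 1) < 1e-12))
    emp <- unclass(z) / rowSums(unclass(z))
    lo <- pmin(emp, 1 / ncol(z)) - 1e-12
    hi <- pmax(emp, 1 / ncol(z)) + 1e-12
    expect_true(all(p >= lo & p <= hi))
  }
})

test_that("growing smoothing constants pull probabilities towards 1/K", {
  z <- count_matrix(rbind(c(0, 9), c(40, 2)))
  k <- ncol(z)
  dist_to_uniform <- sapply(c(1, 10, 1000), function(cc)
    max(abs(laplace_smooth(z, cc) - 1 / k)))
  expect_true(all(diff(dist_to_uniform) < 0))
  expect_lt(dist_to_uniform[3], 1e-2)
})

test_that("arcsin and logit transforms are exact and monotone", {
  p <- laplace_smooth(count_matrix(rbind(c(0, 9), c(5, 5))), 1)
  ya <- proportion_transform(p, "arcsin")
  yl <- proportion_transform(p, "logit")
  expect_equal(unname(ya[2, 1]), asin(sqrt(0.5)))
  expect_equal(unname(yl[2, 1]), 0)
  # p = 0.25 -> arcsin(sqrt(0.25)) = pi/6
  q <- structure(matrix(c(0.25, 0.5), 1, 2), class = class(matrix()))
  expect_equal(unname(proportion_transform(q, "arcsin")[1, 1]), pi / 6)
  expect_error(proportion_transform(matrix(c(0, 0.5), 1, 2)), "strictly")
  set.seed(4)
  pr <- sort(runif(50, 0.01, 0.99))
  pm <- matrix(pr, 1)
  expect_true(all(diff(proportion_transform(pm, "arcsin")[1, ]) > 0))
  expect_true(all(diff(proportion_transform(pm, "logit")[1, ]) > 0))
})

test_that("log transform adds the pseudo-count before the natural log", {
  z <- count_matrix(rbind(c(0, 1), c(3, 7)))
  y <- log_transform(z, 1)
  expect_equal(unname(unclass(y)), log(unclass(z) + 1), ignore_attr = TRUE)
  expect_equal(unname(y[1, 1]), 0)
  expect_equal(unname(y[1, 2]), log(2))
  expect_error(log_transform(z, 0), "pseudo_count")
})

test_that("Box-Cox reduces to identity/log at fixed lambda and maximizes the profile likelihood", {
  z <- toy_counts(10, 3, seed = 6)
  y1 <- boxcox_transform(z, lambda = 1)
  expect_equal(unname(unclass(y1)), unname(unclass(z) + 0),
               ignore_attr = TRUE)
  y0 <- boxcox_transform(z, lambda = 0)
  expect_equal(unname(unclass(y0)), unname(unclass(log_transform(z, 1))),
               ignore_attr = TRUE)
  # estimated lambda agrees with an independent grid search of the
  # profile log-likelihood, and is near 0 for log-normal-ish data
  set.seed(7)
  zl <- count_matrix(matrix(round(rlnorm(200, 4, 0.7)), 200, 1))
  fitted <- boxcox_transform(zl)
  lam_hat <- attr(fitted, "params")$lambda[[1]]
  grid <- seq(-2, 2, by = 0.005)
  yv <- unclass(zl)[, 1] + 1
  ll <- vapply(grid, function(l) {
    yt <- if (abs(l) < 1e-12) log(yv) else (yv^l - 1) / l
    -length(yv) / 2 * log(mean((yt - mean(yt))^2)) + (l - 1) * sum(log(yv))
  }, numeric(1))
  expect_lt(abs(lam_hat - grid[which.max(ll)]), 0.01)
  expect_lt(abs(lam_hat), 0.3)
  expect_warning(boxcox_transform(count_matrix(matrix(5L, 4, 1))),
                 "constant")
})

test_that("Blom transform maps ranks to normal scores", {
  z <- count_matrix(rbind(c(3), c(10)))
  y <- blom_transform(z)
  expect_equal(unname(y[, 1]), c(-0.5894558, 0.5894558), tolerance = 1e-6)
  # constant column -> midranks -> zero column
  zc <- count_matrix(matrix(7L, 5, 1))
  expect_equal(unname(unclass(blom_transform(zc))[, 1]), rep(0, 5))
  set.seed(8)
  zr <- count_matrix(matrix(rpois(40, 30), 20, 2))
  yr <- blom_transform(zr)
  expect_true(all(abs(colMeans(unclass(yr))) < 0.05))
  # the transform depends only on ranks: squaring counts changes nothing
  zsq <- count_matrix(unclass(zr)^2)
  expect_equal(unclass(blom_transform(zsq)), unclass(blom_transform(zr)),
               ignore_attr = TRUE)
})

test_that("transform dispatcher composes smoothing with proportion transforms", {
  z <- toy_counts(6, 4, seed = 10)
  ya <- transform_counts(z, "arcsin")
  expect_equal(unname(unclass(ya)),
               unname(asin(sqrt(unclass(laplace_smooth(z, 1))))),
               ignore_attr = TRUE)
  expect_equal(attr(transform_counts(z, "blom"), "method"), "blom")
  expect_equal(unname(unclass(transform_counts(z, "none"))),
               unname(unclass(z) + 0), ignore_attr = TRUE)
})
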