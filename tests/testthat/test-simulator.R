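test_that("coefficient simulation honours pattern budgets and magnitudes", {
  cfg0 <- simulation_config(n = 10, m = 5, k = 8, n_assoc = 0, seed = 1)
  set.seed(1)
  expect_true(all(simulate_coefficients(cfg0)$b_true == 0))
  # Exponential magnitudes: mean |beta| ~ 1/rate; signs balanced
  cfg <- simulation_config(n = 10, m = 100, k = 200, n_assoc = 10000,
                           effect_rate = 2, seed = 2)
  set.seed(2)
  tr <- simulate_coefficients(cfg)
  nz <- tr$b_true[tr$b_true != 0]
  expect_equal(length(nz), 10000L)
  expect_lt(abs(mean(abs(nz)) - 0.5), 3 * 0.5 / sqrt(10000))
  expect_lt(abs(mean(nz > 0) - 0.5), 3 * 0.5 / sqrt(10000))
  # hotspots hit ceiling(0.1 K) transcripts; polygenic ceiling(0.1 M) markers
  cfgh <- simulation_config(n = 10, m = 20, k = 30, n_assoc = 5,
                            n_hotspots = 2, n_polygenic = 1, seed = 3)
  set.seed(3)
  trh <- simulate_coefficients(cfgh)
  for (j in trh$hotspot_markers)
    expect_gte(sum(trh$b_true[j, ] != 0), 3)
  for (t in trh$polygenic_transcripts)
    expect_gte(sum(trh$b_true[, t] != 0), 2)
  expect_error(simulate_coefficients(
    simulation_config(n = 10, m = 3, k = 3, n_assoc = 10, seed = 1)),
    "budget")
})

test_that("simulated genotypes follow Hardy-Weinberg at the drawn MAF", {
  cfg <- simulation_config(n = 10000, m = 3, k = 2, maf_range = c(0.5, 0.5),
                           seed = 4)
  set.seed(4)
  x <- simulate_genotypes(cfg)
  freqs <- table(factor(unclass(x)[, 1], levels = 0:2)) / 10000
  expect_lt(max(abs(freqs - c(0.25, 0.5, 0.25))), 3 * 0.5 / sqrt(10000))
  cfg2 <- simulation_config(n = 10000, m = 2, k = 2,
                            maf_range = c(0.05, 0.05), seed = 5)
  set.seed(5)
  x2 <- simulate_genotypes(cfg2)
  expect_lt(abs(mean(maf(x2)) - 0.05), 3 * sqrt(0.05 * 0.95 / 20000))
})

test_that("genotype noise resamples entries at the expected rate", {
  cfg <- simulation_config(n = 4000, m = 5, k = 2, maf_range = c(0.3, 0.3),
                           noise_geno = 1, seed = 6)
  set.seed(6)
  x1 <- simulate_genotypes(cfg)
  # resampling from the same Binomial(2, p): mismatch prob 1 - sum P(g)^2
  p <- 0.3
  pg <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  cfg0 <- simulation_config(n = 4000, m = 5, k = 2, maf_range = c(0.3, 0.3),
                            noise_geno = 0, seed = 6)
  set.seed(6)
  x0 <- simulate_genotypes(cfg0)
  flip_rate <- mean(unclass(x1) != unclass(x0))
  expect_lt(abs(flip_rate - (1 - sum(pg^2))), 0.03)
})

test_that("simulated counts match their target dispersion regime", {
  cfg <- simulation_config(n = 2000, m = 3, k = 40, n_assoc = 0,
                           overdispersed = FALSE, seed = 7)
  set.seed(7)
  tr <- simulate_coefficients(cfg)
  x <- simulate_genotypes(cfg)
  z <- simulate_counts(x, tr, cfg)
  zv <- unclass(z)
  # Poisson: index of dispersion ~ 1
  iod <- apply(zv, 2, var) / colMeans(zv)
  expect_lt(mean(abs(iod - 1)), 0.15)
  expect_lt(max(abs(colMeans(zv) / attr(z, "base_mean") - 1)), 0.25)
  cfg2 <- simulation_config(n = 2000, m = 3, k = 40, n_assoc = 0,
                            overdispersed = TRUE, seed = 8)
  set.seed(8)
  tr2 <- simulate_coefficients(cfg2)
  x2 <- simulate_genotypes(cfg2)
  z2 <- simulate_counts(x2, tr2, cfg2)
  zv2 <- unclass(z2)
  expect_gte(mean(apply(zv2, 2, var) > colMeans(zv2)), 0.95)
})

test_that("a log-2 effect quadruples the mean between opposite homozygotes", {
  cfg <- simulation_config(n = 20000, m = 1, k = 1, n_assoc = 0,
                           maf_range = c(0.5, 0.5), nb_mean_log_sd = 0,
                           overdispersed = FALSE, seed = 9)
  set.seed(9)
  tr <- simulate_coefficients(cfg)
  tr$b_true[1, 1] <- log(2)
  x <- simulate_genotypes(cfg)
  z <- simulate_counts(x, tr, cfg)
  g <- unclass(x)[, 1]
  ratio <- mean(unclass(z)[g == 2, 1]) / mean(unclass(z)[g == 0, 1])
  expect_lt(abs(ratio - 4), 0.25)
})

test_that("datasets are a deterministic function of the configuration", {
  cfg <- simulation_config(n = 30, m = 8, k = 10, n_assoc = 4, seed = 10)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(unclass(d1$genotypes), unclass(d2$genotypes))
  expect_identical(unclass(d1$counts), unclass(d2$counts))
  expect_identical(d1$truth$b_true, d2$truth$b_true)
  # persisted TSVs + truth JSON round-trip exactly
  dir <- tempfile()
  simulate_dataset(cfg, out_dir = dir)
  g <- load_genotypes(file.path(dir, "genotypes.tsv"), "tsv")
  z <- load_counts(file.path(dir, "counts.tsv"))
  expect_identical(strip_mat(g), strip_mat(d1$genotypes))
  expect_identical(strip_mat(z), strip_mat(d1$counts))
  tr <- read_truth_json(file.path(dir, "truth.json"))
  expect_equal(tr$b_true, d1$truth$b_true, tolerance = 1e-12)
  expect_identical(tr$config$n_assoc, cfg$n_assoc)
})

test_that("the benchmark panel shape is representable", {
  cfg <- simulation_config(n = 250, m = 100, k = 1000, n_assoc = 50, seed = 11)
  d <- simulate_dataset(cfg)
  expect_equal(dim(d$genotypes), c(250L, 100L))
  expect_equal(dim(d$counts), c(250L, 1000L))
  expect_equal(dim(d$truth$b_true), c(100L, 1000L))
})
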