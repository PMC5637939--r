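#' Simulation settings
#'
#' Defines the generating conditions for artificial (genotype, count,
#' effect) triplets. The defaults emulate the statistical structure of
#' population genotype panels and lymphoblastoid expression profiles
#' without template files: marker MAFs are Uniform(0.05, 0.5), per-gene
#' base means LogNormal(log 100, 1) and per-gene NB dispersions
#' Gamma(2, 0.2); all are exposed here so users can substitute their own
#' template-derived values. Effects act multiplicatively on the NB mean
#' through `exp(x beta)` with mean-centered dosages, so `beta` is on the
#' log scale.
#'
#' @param n,m,k sample, marker and transcript counts (defaults M = 100,
#'   K = 1000, the benchmark panel shape).
#' @param n_assoc number of uniformly placed nonzero associations.
#' @param n_hotspots markers that each affect `ceiling(0.1 K)` transcripts.
#' @param n_polygenic transcripts each affected by `ceiling(0.1 M)` markers.
#' @param effect_rate rate of the Exponential distribution of effect
#'   magnitudes (mean effect = 1 / rate); signs are independent fair coin
#'   flips.
#' @param maf_range interval of marker minor-allele frequencies.
#' @param nb_mean_log_mu,nb_mean_log_sd log-Normal parameters of per-gene
#'   base means.
#' @param nb_dispersion_shape,nb_dispersion_rate Gamma parameters of
#'   per-gene NB dispersions.
#' @param overdispersed draw counts NB (`TRUE`) or Poisson (`FALSE`).
#' @param noise_expr fraction of count entries contaminated by a
#'   multiplicative Uniform(1/10, 10) outlier factor.
#' @param noise_geno fraction of genotype entries resampled from their
#'   marker's Binomial(2, maf) distribution.
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n = 250, m = 100, k = 1000, n_assoc = 50,
                              n_hotspots = 0, n_polygenic = 0,
                              effect_rate = 1,
                              maf_range = c(0.05, 0.5),
                              nb_mean_log_mu = log(100), nb_mean_log_sd = 1,
                              nb_dispersion_shape = 2,
                              nb_dispersion_rate = 0.2,
                              overdispersed = TRUE,
                              noise_expr = 0, noise_geno = 0, seed = 1) {
  stopifnot(n >= 2, m >= 1, k >= 1, n_assoc >= 0,
            n_hotspots >= 0, n_polygenic >= 0, effect_rate > 0,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            nb_mean_log_sd >= 0, nb_dispersion_shape > 0,
            nb_dispersion_rate > 0,
            noise_expr >= 0, noise_expr <= 1,
            noise_geno >= 0, noise_geno <= 1)
  structure(list(n = as.integer(n), m = as.integer(m), k = as.integer(k),
                 n_assoc = as.integer(n_assoc),
                 n_hotspots = as.integer(n_hotspots),
                 n_polygenic = as.integer(n_polygenic),
                 effect_rate = effect_rate, maf_range = maf_range,
                 nb_mean_log_mu = nb_mean_log_mu,
                 nb_mean_log_sd = nb_mean_log_sd,
                 nb_dispersion_shape = nb_dispersion_shape,
                 nb_dispersion_rate = nb_dispersion_rate,
                 overdispersed = isTRUE(overdispersed),
                 noise_expr = noise_expr, noise_geno = noise_geno,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate the true coefficient matrix
#'
#' Places nonzero effects in three patterns: `n_hotspots` markers each hit
#' `ceiling(0.1 K)` random transcripts, `n_polygenic` transcripts are each
#' hit by `ceiling(0.1 M)` random markers, and `n_assoc` further
#' associations fall uniformly at random among the remaining pairs.
#' Magnitudes are i.i.d. Exponential(`effect_rate`) with independent
#' random signs.
#'
#' @param cfg a [simulation_config()].
#' @return a list of class `simulation_truth` with `b_true` (M x K),
#'   `hotspot_markers`, `polygenic_transcripts` and the config.
#' @export
simulate_coefficients <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  m <- cfg$m; k <- cfg$k
  budget <- cfg$n_assoc + cfg$n_hotspots * ceiling(0.1 * k) +
    cfg$n_polygenic * ceiling(0.1 * m)
  if (budget > m * k)
    stop("association budget exceeds the number of marker-transcript pairs")
  if (cfg$n_hotspots > m) stop("more hotspots than markers")
  if (cfg$n_polygenic > k) stop("more polygenic transcripts than transcripts")
  nonzero <- matrix(FALSE, m, k)
  hot <- if (cfg$n_hotspots > 0) sample.int(m, cfg$n_hotspots) else integer(0)
  for (j in hot)
    nonzero[j, sample.int(k, ceiling(0.1 * k))] <- TRUE
  poly <- if (cfg$n_polygenic > 0) sample.int(k, cfg$n_polygenic) else integer(0)
  for (t in poly)
    nonzero[sample.int(m, ceiling(0.1 * m)), t] <- TRUE
  free <- which(!nonzero)
  if (cfg$n_assoc > length(free))
    stop("association budget exceeds the remaining free pairs")
  if (cfg$n_assoc > 0)
    nonzero[sample(free, cfg$n_assoc)] <- TRUE
  b <- matrix(0, m, k)
  nn <- sum(nonzero)
  if (nn > 0) {
    b[nonzero] <- stats::rexp(nn, rate = cfg$effect_rate) *
      sample(c(-1, 1), nn, replace = TRUE)
  }
  dimnames(b) <- list(paste0("marker", seq_len(m)),
                      paste0("transcript", seq_len(k)))
  structure(list(b_true = b, hotspot_markers = sort(hot),
                 polygenic_transcripts = sort(poly), config = cfg),
            class = "simulation_truth")
}

#' Simulate a genotype matrix
#'
#' Each marker draws a MAF uniformly from `maf_range` and samples dosages
#' `x_ij ~ Binomial(2, maf_j)` (Hardy-Weinberg-like, a stand-in for
#' population-panel templates). With probability `noise_geno` an entry is
#' resampled from its marker's dosage distribution.
#'
#' @param cfg a [simulation_config()].
#' @return a [genotype_matrix()] with attribute `maf_true`.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- cfg$n; m <- cfg$m
  maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  x <- matrix(stats::rbinom(n * m, 2, rep(maf, each = n)), n, m)
  if (cfg$noise_geno > 0) {
    hit <- matrix(stats::runif(n * m) < cfg$noise_geno, n, m)
    x[hit] <- stats::rbinom(sum(hit), 2,
                            rep(maf, each = n)[as.vector(hit)])
  }
  g <- genotype_matrix(x, paste0("sample", seq_len(n)),
                       paste0("marker", seq_len(m)))
  attr(g, "maf_true") <- maf
  g
}

#' Simulate a read-count matrix
#'
#' Per transcript, a base mean `mu_k ~ LogNormal` and NB dispersion
#' `phi_k ~ Gamma` are drawn; the per-sample mean is
#' `mu_k exp(xc_i' beta_k)` with mean-centered dosages `xc` (so the base
#' mean is the geometric-mean expression), and counts are NB
#' (`variance = mean + mean^2 / phi`) or Poisson when `overdispersed =
#' FALSE`. With probability `noise_expr` an entry is multiplied by a
#' Uniform(1/10, 10) outlier factor and rounded.
#'
#' @param x a [genotype_matrix()].
#' @param truth a `simulation_truth` from [simulate_coefficients()].
#' @param cfg a [simulation_config()].
#' @return a [count_matrix()] with attributes `base_mean` and `dispersion`.
#' @export
simulate_counts <- function(x, truth, cfg) {
  stopifnot(inherits(cfg, "simulation_config"),
            inherits(truth, "simulation_truth"))
  n <- nrow(x); k <- cfg$k
  stopifnot(ncol(x) == nrow(truth$b_true), ncol(truth$b_true) == k)
  base_mean <- stats::rlnorm(k, cfg$nb_mean_log_mu, cfg$nb_mean_log_sd)
  phi <- stats::rgamma(k, cfg$nb_dispersion_shape,
                       rate = cfg$nb_dispersion_rate)
  xc <- scale(raw_values(x), center = TRUE, scale = FALSE)
  mean_mat <- exp(xc %*% truth$b_true)
  mean_mat <- sweep(mean_mat, 2, base_mean, `*`)
  if (any(mean_mat > 1e9))
    stop("simulated mean count exceeds 1e9; use smaller effects or means")
  z <- if (cfg$overdispersed) {
    matrix(stats::rnbinom(n * k, size = rep(phi, each = n),
                          mu = as.vector(mean_mat)), n, k)
  } else {
    matrix(stats::rpois(n * k, as.vector(mean_mat)), n, k)
  }
  if (cfg$noise_expr > 0) {
    hit <- which(stats::runif(n * k) < cfg$noise_expr)
    fac <- stats::runif(length(hit), 0.1, 10)
    z[hit] <- round(z[hit] * fac)
  }
  zc <- count_matrix(z, rownames(x), colnames(truth$b_true))
  attr(zc, "base_mean") <- base_mean
  attr(zc, "dispersion") <- phi
  zc
}

#' Simulate a full (genotypes, counts, truth) triplet
#'
#' Composes [simulate_coefficients()], [simulate_genotypes()] and
#' [simulate_counts()] under the configuration's seed; the result is a
#' deterministic function of `cfg`. When `out_dir` is given, writes
#' `genotypes.tsv`, `counts.tsv` and `truth.json`.
#'
#' @param cfg a [simulation_config()].
#' @param out_dir optional output directory.
#' @return list with `genotypes`, `counts`, `truth`.
#' @export
simulate_dataset <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  truth <- simulate_coefficients(cfg)
  x <- simulate_genotypes(cfg)
  z <- simulate_counts(x, truth, cfg)
  out <- list(genotypes = x, counts = z, truth = truth)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_matrix(x, file.path(out_dir, "genotypes.tsv"))
    write_matrix(z, file.path(out_dir, "counts.tsv"))
    write_truth_json(truth, file.path(out_dir, "truth.json"))
  }
  out
}

#' Write / read simulation truth as JSON
#'
#' @param truth a `simulation_truth`.
#' @param path JSON path.
#' @return `path` invisibly (`write_truth_json`); the reconstructed
#'   `simulation_truth` (`read_truth_json`).
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  cfg <- truth$config
  obj <- list(
    b_true = list(values = unname(as.vector(truth$b_true)),
                  nrow = nrow(truth$b_true), ncol = ncol(truth$b_true),
                  marker_ids = rownames(truth$b_true),
                  transcript_ids = colnames(truth$b_true)),
    hotspot_markers = truth$hotspot_markers,
    polygenic_transcripts = truth$polygenic_transcripts,
    config = unclass(cfg))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  b <- matrix(obj$b_true$values, obj$b_true$nrow, obj$b_true$ncol,
              dimnames = list(obj$b_true$marker_ids,
                              obj$b_true$transcript_ids))
  cfgl <- obj$config
  cfg <- simulation_config(
    n = cfgl$n, m = cfgl$m, k = cfgl$k, n_assoc = cfgl$n_assoc,
    n_hotspots = cfgl$n_hotspots, n_polygenic = cfgl$n_polygenic,
    effect_rate = cfgl$effect_rate, maf_range = cfgl$maf_range,
    nb_mean_log_mu = cfgl$nb_mean_log_mu,
    nb_mean_log_sd = cfgl$nb_mean_log_sd,
    nb_dispersion_shape = cfgl$nb_dispersion_shape,
    nb_dispersion_rate = cfgl$nb_dispersion_rate,
    overdispersed = cfgl$overdispersed, noise_expr = cfgl$noise_expr,
    noise_geno = cfgl$noise_geno, seed = cfgl$seed)
  structure(list(b_true = b,
                 hotspot_markers = as.integer(obj$hotspot_markers),
                 polygenic_transcripts = as.integer(obj$polygenic_transcripts),
                 config = cfg),
            class = "simulation_truth")
}
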