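# shared fixture builders; everything is generated in code at test time

# matrix values + dimnames only (drops classes and extra attributes)
strip_mat <- function(x) {
  x <- unclass(x)
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}

toy_genotypes <- function(n = 6, m = 4, seed = 1, p = 0.3) {
  set.seed(seed)
  genotype_matrix(matrix(rbinom(n * m, 2, p), n, m,
                         dimnames = list(paste0("s", seq_len(n)),
                                         paste0("m", seq_len(m)))))
}

toy_counts <- function(n = 6, k = 5, seed = 2, lambda = 50) {
  set.seed(seed)
  count_matrix(matrix(rpois(n * k, lambda), n, k,
                      dimnames = list(paste0("s", seq_len(n)),
                                      paste0("g", seq_len(k)))))
}

write_tsv_fixture <- function(header, rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, character(1), collapse = "\t")), path)
  path
}

# a small VCF: three clean bi-allelic SNVs (the second with ALT as the
# major allele), one multi-allelic record and one record with a missing
# genotype
toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", "s4", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", "0/1", sep = "\t"),
    paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "1/1", "1/1", "0/1", "1/1", sep = "\t"),
    paste("1", "300", "rs3", "G", "A", ".", "PASS", ".", "GT",
          "0/0", "0/0", "0/1", "./.", sep = "\t"),
    paste("1", "400", "rs4", "T", "A,C", ".", "PASS", ".", "GT",
          "0/1", "0/2", "1/2", "0/0", sep = "\t")),
    path)
  path
}

# self-simulated datasets: data generated from exactly the model each
# fitter assumes, with effects of magnitude 1 and known offsets
selfsim_effects <- function(m, k, n_effects, seed) {
  set.seed(seed)
  b <- matrix(0, m, k)
  b[sample(m * k, n_effects)] <- sample(c(-1, 1), n_effects, replace = TRUE)
  b
}

selfsim_normal <- function(n = 300, m = 10, k = 20, n_effects = 5,
                           sigma = 0.1, seed = 1) {
  b <- selfsim_effects(m, k, n_effects, seed)
  x <- genotype_matrix(matrix(rbinom(n * m, 2, 0.3), n, m))
  xc <- scale(unclass(x), center = TRUE, scale = FALSE)
  y <- xc %*% b + matrix(rnorm(n * k, 0, sigma), n, k)
  list(x = x, y = transformed_matrix(y), b = b)
}

selfsim_pois <- function(n = 300, m = 10, k = 20, n_effects = 5,
                         sigma = 0.4, base_log_mean = log(100),
                         depth_sd = 0.3, seed = 1) {
  b <- selfsim_effects(m, k, n_effects, seed)
  x <- genotype_matrix(matrix(rbinom(n * m, 2, 0.3), n, m))
  xc <- scale(unclass(x), center = TRUE, scale = FALSE)
  depth <- rnorm(n, 0, depth_sd)
  lat <- sweep(sweep(xc %*% b, 2, base_log_mean, `+`), 1, depth, `+`) +
    matrix(rnorm(n * k, 0, sigma), n, k)
  z <- count_matrix(matrix(rpois(n * k, exp(as.vector(lat))), n, k))
  list(x = x, z = z, b = b, offset = depth)
}

selfsim_nbin <- function(n = 500, m = 10, k = 20, n_effects = 5, r = 10,
                         base_mean = 100, depth_sd = 0.3, seed = 1) {
  b <- selfsim_effects(m, k, n_effects, seed)
  x <- genotype_matrix(matrix(rbinom(n * m, 2, 0.3), n, m))
  xc <- scale(unclass(x), center = TRUE, scale = FALSE)
  depth <- rnorm(n, 0, depth_sd)
  psi <- sweep(sweep(xc %*% b, 2, log(base_mean / r), `+`), 1, depth, `+`)
  z <- count_matrix(matrix(
    rnbinom(n * k, size = r, mu = r * exp(as.vector(psi))), n, k))
  list(x = x, z = z, b = b, offset = depth, r = r)
}

selfsim_bin <- function(n = 300, m = 10, k = 20, n_effects = 5,
                        sigma = 0.3, seed = 1) {
  b <- selfsim_effects(m, k, n_effects, seed)
  x <- genotype_matrix(matrix(rbinom(n * m, 2, 0.3), n, m))
  xc <- scale(unclass(x), center = TRUE, scale = FALSE)
  lib <- round(runif(n, 2000, 4000))
  lat <- sweep(xc %*% b, 2, qlogis(1 / k), `+`) +
    matrix(rnorm(n * k, 0, sigma), n, k)
  z <- matrix(rbinom(n * k, size = rep(lib, k), prob = plogis(as.vector(lat))),
              n, k)
  list(x = x, z = count_matrix(z), b = b)
}
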