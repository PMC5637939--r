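#' Per-sample size factors
#'
#' Library-depth scaling factors used as offsets by the count models and,
#' optionally, to normalize counts before Laplace smoothing. `total_count`
#' divides each library size by the mean library size, so the factors
#' average to 1. `median_of_ratios` is the standard median-of-ratios
#' estimator (per-sample median of counts over the per-transcript geometric
#' mean, restricted to transcripts with all-positive counts), rescaled to
#' geometric mean 1; when no transcript has all-positive counts it falls
#' back to `total_count` with a warning.
#'
#' @param z a [count_matrix()].
#' @param method `"total_count"` or `"median_of_ratios"`.
#' @return positive numeric vector of length N.
#' @export
size_factors <- function(z, method = c("total_count", "median_of_ratios")) {
  method <- match.arg(method)
  zv <- raw_values(z)
  lib <- rowSums(zv)
  if (any(lib <= 0)) stop("every sample must have a positive library size")
  if (method == "median_of_ratios") {
    pos <- colSums(zv > 0) == nrow(zv)
    if (!any(pos)) {
      warning("no transcript with all-positive counts; ",
              "falling back to total-count size factors")
      method <- "total_count"
    } else {
      logz <- log(zv[, pos, drop = FALSE])
      loggeo <- colMeans(logz)
      sf <- apply(logz, 1, function(r) exp(stats::median(r - loggeo)))
      return(sf / exp(mean(log(sf))))
    }
  }
  lib / mean(lib)
}

#' Laplace (additive) smoothing of read counts
#'
#' Views each sample as a multinomial experiment assigning reads to K
#' transcripts and returns the smoothed mapping probabilities
#' `p_ik = (z_ik + c) / (sum_k z_ik + c K)`. Each smoothed probability lies
#' strictly in (0, 1), rows sum to 1 exactly, and each entry lies between
#' the empirical proportion `z_ik / sum_k z_ik` and the uniform probability
#' `1/K` — the smaller the library, the stronger the pull towards `1/K`.
#'
#' @param z a [count_matrix()], or a non-negative matrix of (possibly
#'   size-factor normalized) counts.
#' @param c positive smoothing constant (default 1).
#' @param normalize if `TRUE`, divide counts by total-count size factors
#'   before smoothing.
#' @return numeric matrix of probabilities with attributes `smoothing_constant`
#'   and class `smoothed_matrix`.
#' @export
laplace_smooth <- function(z, c = 1, normalize = FALSE) {
  if (!is.numeric(c) || length(c) != 1 || !is.finite(c) || c <= 0)
    stop("the smoothing constant c must be a positive number")
  zv <- raw_values(z)
  if (any(zv < 0)) stop("counts must be non-negative")
  if (normalize) {
    lib <- rowSums(zv)
    if (any(lib <= 0)) stop("every sample must have a positive library size")
    zv <- zv / (lib / mean(lib))
  }
  k <- ncol(zv)
  p <- (zv + c) / (rowSums(zv) + c * k)
  dimnames(p) <- dimnames(zv)
  structure(p, smoothing_constant = c,
            class = c("smoothed_matrix", class(matrix())))
}

#' Arcsin / logit transforms of smoothed proportions
#'
#' Maps smoothed mapping probabilities to the real line (logit,
#' `log(p / (1 - p))`) or to `(0, pi/2)` (arcsin, `asin(sqrt(p))` — the
#' classical variance-stabilizing transform for proportions). Both are
#' strictly increasing, so ordering within a transcript is preserved.
#'
#' @param p a matrix of probabilities strictly inside (0, 1), e.g. from
#'   [laplace_smooth()].
#' @param method `"arcsin"` or `"logit"`.
#' @return a [transformed_matrix()].
#' @export
proportion_transform <- function(p, method = c("arcsin", "logit")) {
  method <- match.arg(method)
  pv <- raw_values(p)
  if (any(pv <= 0) || any(pv >= 1))
    stop("proportions must lie strictly inside (0, 1)")
  y <- if (method == "arcsin") asin(sqrt(pv)) else log(pv / (1 - pv))
  transformed_matrix(y, method = method,
                     params = list(
                       smoothing_constant = attr(p, "smoothing_constant")))
}

#' Shifted-log transform of counts
#'
#' `y = log(z + pseudo_count)`, natural logarithm; the pseudo-count avoids
#' infinities at zero counts.
#'
#' @param z a [count_matrix()].
#' @param pseudo_count positive shift (default 1).
#' @return a [transformed_matrix()].
#' @export
log_transform <- function(z, pseudo_count = 1) {
  stopifnot(is.numeric(pseudo_count), length(pseudo_count) == 1,
            pseudo_count > 0)
  zv <- raw_values(z)
  transformed_matrix(log(zv + pseudo_count), method = "log",
                     params = list(pseudo_count = pseudo_count))
}

# profile log-likelihood of the one-parameter Box-Cox family for a single
# positive vector (intercept-only model)
boxcox_profile_loglik <- function(y, lambda) {
  n <- length(y)
  yt <- if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
  ssq <- sum((yt - mean(yt))^2)
  if (ssq <= 0) return(-Inf)
  -n / 2 * log(ssq / n) + (lambda - 1) * sum(log(y))
}

#' Per-transcript Box-Cox transform
#'
#' Adds a single pseudo-count to avoid zeros, then transforms each
#' transcript with the one-parameter Box-Cox family
#' `y = ((z + 1)^lambda - 1) / lambda` (with the `log(z + 1)` limit at
#' `lambda = 0`). Each transcript's `lambda` maximizes the profile
#' log-likelihood over `[-2, 2]`; per-transcript estimates accommodate the
#' gene-wise mean-variance heterogeneity of RNA-seq. Constant transcripts
#' have no defined `lambda` and are emitted as zero columns with a warning.
#'
#' @param z a [count_matrix()].
#' @param lambda optional fixed lambda applied to every transcript (mostly
#'   for testing); `NULL` (default) estimates per transcript.
#' @return a [transformed_matrix()] with per-transcript `lambda` in
#'   `params$lambda`.
#' @export
boxcox_transform <- function(z, lambda = NULL) {
  zv <- raw_values(z) + 1
  k <- ncol(zv)
  lam <- numeric(k)
  out <- matrix(0, nrow(zv), k, dimnames = dimnames(zv))
  const_cols <- integer(0)
  for (j in seq_len(k)) {
    y <- zv[, j]
    if (max(y) == min(y)) {
      const_cols <- c(const_cols, j)
      lam[j] <- NA_real_
      next
    }
    lam[j] <- if (is.null(lambda)) {
      stats::optimize(function(l) boxcox_profile_loglik(y, l),
                      interval = c(-2, 2), maximum = TRUE,
                      tol = 1e-6)$maximum
    } else lambda
    out[, j] <- if (abs(lam[j]) < 1e-12) log(y) else (y^lam[j] - 1) / lam[j]
  }
  if (length(const_cols) > 0)
    warning(sprintf(
      "%d constant transcript(s) have undefined Box-Cox lambda; emitted as 0",
      length(const_cols)))
  names(lam) <- colnames(zv)
  transformed_matrix(out, method = "boxcox",
                     params = list(lambda = lam, pseudo_count = 1))
}

#' Blom (rank-based inverse-normal) transform
#'
#' Per transcript, ranks the counts across samples (average ranks for ties)
#' and maps them to standard-normal quantiles using Blom's scores
#' `qnorm((r - 3/8) / (N + 1/4))`. The output depends only on the ranks, so
#' any strictly monotone distortion of a transcript leaves its transform
#' unchanged; a constant transcript maps to the zero column.
#'
#' @param z a [count_matrix()].
#' @return a [transformed_matrix()].
#' @export
blom_transform <- function(z) {
  zv <- raw_values(z)
  if (nrow(zv) < 2) stop("Blom transform needs at least 2 samples")
  n <- nrow(zv)
  y <- apply(zv, 2, function(col) {
    stats::qnorm((rank(col, ties.method = "average") - 3 / 8) / (n + 1 / 4))
  })
  dimnames(y) <- dimnames(zv)
  transformed_matrix(y, method = "blom", params = list(offset = 3 / 8))
}

#' Apply a named transform to a count matrix
#'
#' Convenience dispatcher used by the model-fitting front end and the CLI:
#' `"none"` passes a pre-transformed matrix through, `"log"`, `"boxcox"`
#' and `"blom"` act directly on counts, `"arcsin"` and `"logit"` compose
#' [laplace_smooth()] with [proportion_transform()].
#'
#' @param z a [count_matrix()] (or, for `"none"`, any numeric matrix).
#' @param method one of `"none"`, `"log"`, `"boxcox"`, `"blom"`,
#'   `"arcsin"`, `"logit"`.
#' @param normalize normalize by total-count size factors before Laplace
#'   smoothing (arcsin/logit only).
#' @return a [transformed_matrix()].
#' @export
transform_counts <- function(z, method = c("none", "log", "boxcox", "blom",
                                           "arcsin", "logit"),
                             normalize = FALSE) {
  method <- match.arg(method)
  switch(method,
    none = transformed_matrix(raw_values(z), method = "none"),
    log = log_transform(z),
    boxcox = boxcox_transform(z),
    blom = blom_transform(z),
    arcsin = ,
    logit = proportion_transform(laplace_smooth(z, normalize = normalize),
                                 method = method))
}
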