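#' Matthews correlation coefficient
#'
#' Balanced binary-classification performance of a call matrix against the
#' true nonzero pattern:
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with 0
#' returned when any factor of the denominator is zero.
#'
#' @param called logical matrix (or vector) of calls.
#' @param truth_nonzero logical matrix of true associations, same shape.
#' @return a number in `[-1, 1]`.
#' @export
mcc <- function(called, truth_nonzero) {
  stopifnot(length(called) == length(truth_nonzero))
  called <- as.logical(called); truth_nonzero <- as.logical(truth_nonzero)
  tp <- as.numeric(sum(called & truth_nonzero))
  fp <- as.numeric(sum(called & !truth_nonzero))
  fn <- as.numeric(sum(!called & truth_nonzero))
  tn <- as.numeric(sum(!called & !truth_nonzero))
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom2)
}

#' RMSE of effect sizes among the true positives
#'
#' Both coefficient matrices are first normalized by their own largest
#' absolute entry (so a global gain in the estimates does not count as
#' error), then the root-mean-square difference is taken over the pairs
#' that are both called and truly nonzero. With no true positives the
#' result is `NA` (undefined), not 0.
#'
#' @param b_est,b_true M x K coefficient matrices.
#' @param called,truth_nonzero logical matrices of the same shape.
#' @return non-negative number, or `NA_real_` when there is no true
#'   positive.
#' @export
rmse_true_positives <- function(b_est, b_true, called, truth_nonzero) {
  stopifnot(all(dim(b_est) == dim(b_true)),
            length(called) == length(b_est),
            length(truth_nonzero) == length(b_true))
  tp <- as.logical(called) & as.logical(truth_nonzero)
  if (!any(tp)) return(NA_real_)
  norm_est <- max(abs(b_est)); norm_true <- max(abs(b_true))
  be <- if (norm_est > 0) b_est / norm_est else b_est
  bt <- if (norm_true > 0) b_true / norm_true else b_true
  sqrt(mean((be[tp] - bt[tp])^2))
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between two paired sets of values, penalizing both
#' decorrelation and location/scale shifts:
#' `CCC = 2 cov(a, b) / (var a + var b + (mean a - mean b)^2)`, with
#' population (1/n) variance convention. Two constant vectors give 0 with
#' a warning.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return a number in `[-1, 1]`.
#' @export
ccc <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2,
            all(is.finite(a)), all(is.finite(b)))
  n <- length(a)
  va <- stats::var(a) * (n - 1) / n
  vb <- stats::var(b) * (n - 1) / n
  if (va == 0 && vb == 0) {
    warning("both vectors are constant; concordance undefined, returning 0")
    return(0)
  }
  cab <- stats::cov(a, b) * (n - 1) / n
  2 * cab / (va + vb + (mean(a) - mean(b))^2)
}

#' Benchmark a fit against simulation truth
#'
#' @param fit an `eqtl_fit`.
#' @param truth a `simulation_truth`.
#' @param call_threshold robust-SD multiplier for [call_associations()].
#' @return one-row tibble with the confusion counts, `mcc`, `rmse_tp`,
#'   `tpr` and `ppv`.
#' @export
benchmark_fit <- function(fit, truth, call_threshold = 2.5) {
  stopifnot(inherits(fit, "eqtl_fit"), inherits(truth, "simulation_truth"))
  called <- call_associations(fit$beta_draws, threshold_sd = call_threshold)
  nz <- truth$b_true != 0
  b_est <- coef_median(fit)
  tp <- sum(called & nz); fp <- sum(called & !nz)
  fn <- sum(!called & nz); tn <- sum(!called & !nz)
  tibble::tibble(
    model = fit$model, transform = fit$transform,
    n_tp = tp, n_fp = fp, n_fn = fn, n_tn = tn,
    tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    mcc = mcc(called, nz),
    rmse_tp = rmse_true_positives(b_est, truth$b_true, called, nz))
}

# fit one model (name in normal-transform or count-model vocabulary) on a
# genotype/count pair; transform names select the Normal model
fit_model_by_name <- function(x, z, model, control) {
  normal_transforms <- c("log", "boxcox", "blom", "arcsin", "logit", "none")
  if (model %in% normal_transforms) {
    fit_normal(x, transform_counts(z, model), control = control)
  } else {
    switch(model,
           pois = fit_poisson(x, z, control),
           bin = fit_binomial(x, z, control),
           nbin = fit_nbin(x, z, control),
           normal = fit_normal(x, transform_counts(z, "arcsin"), control),
           stop("unknown model: ", model))
  }
}

#' Simulation benchmark over models, sample sizes and seeds
#'
#' For each (model, N, seed) cell: simulate a dataset, fit, and score
#' MCC / RMSE against the planted truth. Model names are either count
#' models (`"pois"`, `"bin"`, `"nbin"`) or transform names
#' (`"arcsin"`, `"logit"`, `"log"`, `"boxcox"`, `"blom"`) selecting the
#' Normal model on the correspondingly transformed counts.
#'
#' @param models character vector of model names.
#' @param n_values sample sizes to simulate.
#' @param seeds simulation seeds (one dataset per (N, seed), shared by all
#'   models).
#' @param sim_args named list of overrides passed to [simulation_config()].
#' @param control an [mcmc_control()]; its seed is combined with the
#'   simulation seed.
#' @return tibble with one row per (model, n, seed) and the
#'   [benchmark_fit()] columns.
#' @export
benchmark_models <- function(models, n_values, seeds = 1:3,
                             sim_args = list(), control = mcmc_control()) {
  grid <- expand.grid(n = n_values, seed = seeds, stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid) * length(models))
  ctr <- 0
  for (g in seq_len(nrow(grid))) {
    cfg <- do.call(simulation_config,
                   c(list(n = grid$n[g], seed = grid$seed[g]), sim_args))
    dat <- simulate_dataset(cfg)
    for (mod in models) {
      ctr <- ctr + 1
      ctl <- mcmc_control(iterations = control$iterations,
                          burnin = control$burnin,
                          seed = control$seed + 1000L * ctr,
                          adapt_target = control$adapt_target)
      fit <- fit_model_by_name(dat$genotypes, dat$counts, mod, ctl)
      row <- benchmark_fit(fit, dat$truth)
      row$model <- mod
      row$n <- grid$n[g]
      row$seed <- grid$seed[g]
      out[[ctr]] <- row
    }
  }
  dplyr::bind_rows(out)
}

#' Monte Carlo cross-validation of predictive performance
#'
#' Repeatedly splits samples into training and validation sets (default
#' ratio 3:1), fits the requested model on the training samples and scores
#' Lin's concordance between predicted and observed expression on the
#' validation samples. The Normal model is compared on the transformed
#' scale; count models are compared on the `log1p` scale to keep the
#' concordance stable across expression magnitudes. Also records how many
#' associations each repeat calls. A failed repeat is recorded and skipped
#' with a warning.
#'
#' @param x a [genotype_matrix()].
#' @param z a [count_matrix()].
#' @param model model name as in [benchmark_models()].
#' @param repeats number of random splits (default 10).
#' @param ratio training fraction (default 0.75 = 3:1).
#' @param seed split seed; repeat r uses `seed + r`.
#' @param control an [mcmc_control()].
#' @return list of class `eqtl_cv` with a per-repeat tibble (`results`),
#'   the mean concordance (`mean_ccc`) and the model name.
#' @export
monte_carlo_cv <- function(x, z, model = "arcsin", repeats = 10,
                           ratio = 0.75, seed = 1,
                           control = mcmc_control()) {
  stopifnot(repeats >= 1, ratio > 0, ratio < 1)
  n <- nrow(x)
  n_train <- round(n * ratio)
  if (n_train < 2 || n_train >= n)
    stop("sample size too small for the requested split ratio")
  rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    idx <- sample.int(n, n_train)
    res <- tryCatch(
      cv_one_split(x, z, model, idx, control, seed + r),
      error = function(e) {
        warning(sprintf("cross-validation repeat %d failed: %s",
                        r, conditionMessage(e)))
        NULL
      })
    rows[[r]] <- if (is.null(res)) {
      tibble::tibble(repeat_id = r, ccc = NA_real_, n_called = NA_integer_)
    } else {
      tibble::tibble(repeat_id = r, ccc = res$ccc, n_called = res$n_called)
    }
  }
  results <- dplyr::bind_rows(rows)
  structure(list(model = model, results = results,
                 mean_ccc = mean(results$ccc, na.rm = TRUE)),
            class = "eqtl_cv")
}

cv_one_split <- function(x, z, model, idx, control, seed) {
  xv <- raw_values(x); zv <- raw_values(z)
  x_tr <- genotype_matrix(xv[idx, , drop = FALSE],
                          rownames(x)[idx], colnames(x))
  z_tr <- count_matrix(zv[idx, , drop = FALSE], rownames(z)[idx], colnames(z))
  x_va <- genotype_matrix(xv[-idx, , drop = FALSE],
                          rownames(x)[-idx], colnames(x))
  z_va <- zv[-idx, , drop = FALSE]
  ctl <- mcmc_control(control$iterations, control$burnin, seed = seed,
                      adapt_target = control$adapt_target)
  normal_transforms <- c("log", "boxcox", "blom", "arcsin", "logit")
  if (model %in% c(normal_transforms, "normal")) {
    tr <- if (model == "normal") "arcsin" else model
    fit <- fit_normal(x_tr, transform_counts(z_tr, tr), ctl)
    pred <- predict_expression(fit, x_va)
    obs <- raw_values(transform_counts(count_matrix(
      z_va, rownames(z_va), colnames(z_va)), tr))
    cc <- ccc(as.vector(pred), as.vector(obs))
  } else {
    fit <- fit_model_by_name(x_tr, z_tr, model, ctl)
    lib_va <- rowSums(z_va)
    off_va <- log(lib_va / mean(rowSums(zv[idx, , drop = FALSE])))
    pred <- predict_expression(fit, x_va, offset = off_va,
                               lib_sizes = lib_va)
    cc <- ccc(as.vector(log1p(pred)), as.vector(log1p(z_va)))
  }
  list(ccc = cc,
       n_called = sum(call_associations(fit$beta_draws)))
}

#' @export
print.eqtl_cv <- function(x, ...) {
  cat(sprintf("<eqtl_cv: %s, %d repeats, mean CCC %.3f>\n",
              x$model, nrow(x$results), x$mean_ccc))
  invisible(x)
}
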