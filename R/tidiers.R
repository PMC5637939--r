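#' Tidy posterior summaries of a fit
#'
#' Broom-style accessor: one row per marker-transcript pair with the
#' posterior median, central credible interval and call flag.
#'
#' @param x an `eqtl_fit`.
#' @param credible_level central credible mass (default 0.95).
#' @param call_threshold robust-SD multiplier for [call_associations()].
#' @param ... unused.
#' @return a tibble, see [association_table()].
#' @export
tidy.eqtl_fit <- function(x, credible_level = 0.95, call_threshold = 2.5,
                          ...) {
  association_table(x, credible_level = credible_level,
                    call_threshold = call_threshold)
}

#' One-row summary of a fit
#'
#' @param x an `eqtl_fit`.
#' @param ... unused.
#' @return a one-row tibble: model, transform, dimensions, MCMC settings
#'   and the number of called associations.
#' @export
glance.eqtl_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    transform = x$transform,
    n_markers = length(x$marker_ids),
    n_transcripts = length(x$transcript_ids),
    iterations = x$mcmc$iterations,
    burnin = x$mcmc$burnin,
    seed = x$mcmc$seed,
    n_called = sum(call_associations(x$beta_draws)))
}

#' Tidy per-repeat cross-validation results
#'
#' @param x an `eqtl_cv` from [monte_carlo_cv()].
#' @param ... unused.
#' @return the per-repeat tibble with a `model` column.
#' @export
tidy.eqtl_cv <- function(x, ...) {
  dplyr::mutate(x$results, model = x$model, .before = 1)
}

#' @rdname tidy.eqtl_cv
#' @export
glance.eqtl_cv <- function(x, ...) {
  tibble::tibble(model = x$model, repeats = nrow(x$results),
                 mean_ccc = x$mean_ccc,
                 mean_n_called = mean(x$results$n_called, na.rm = TRUE))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
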