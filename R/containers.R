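#' Genotype dosage matrix
#'
#' Wraps an N x M integer matrix of additive-coded minor-allele dosages
#' (entries in \{0, 1, 2\}), with sample identifiers on rows and marker
#' identifiers on columns.
#'
#' @param values integer matrix (samples x markers) with entries in
#'   \{0, 1, 2\}.
#' @param sample_ids,marker_ids character vectors of unique identifiers;
#'   default to the dimnames of `values`.
#' @return an object of class `genotype_matrix` (an integer matrix with
#'   dimnames).
#' @examples
#' g <- genotype_matrix(rbind(s1 = c(m1 = 0, m2 = 1, m3 = 2),
#'                            s2 = c(1, 1, 0)))
#' maf(g)
#' @export
genotype_matrix <- function(values, sample_ids = rownames(values),
                            marker_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(values)))
  if (is.null(marker_ids)) marker_ids <- paste0("marker", seq_len(ncol(values)))
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers")
  if (anyDuplicated(marker_ids)) stop("duplicate marker identifiers")
  if (length(sample_ids) != nrow(values) || length(marker_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  if (anyNA(values) || !all(values %in% c(0L, 1L, 2L)))
    stop("genotype dosages must all lie in {0, 1, 2}")
  storage.mode(values) <- "integer"
  dimnames(values) <- list(sample_ids, marker_ids)
  class(values) <- c("genotype_matrix", class(matrix()))
  values
}

#' Read-count matrix
#'
#' Wraps an N x K matrix of non-negative integer read counts (samples x
#' transcripts).
#'
#' @param values non-negative integer matrix (samples x transcripts).
#' @param sample_ids,transcript_ids character identifier vectors; default to
#'   the dimnames of `values`.
#' @return an object of class `count_matrix`.
#' @examples
#' z <- count_matrix(rbind(s1 = c(g1 = 3, g2 = 0), s2 = c(10, 7)))
#' @export
count_matrix <- function(values, sample_ids = rownames(values),
                         transcript_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(values)))
  if (is.null(transcript_ids))
    transcript_ids <- paste0("transcript", seq_len(ncol(values)))
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers")
  if (anyDuplicated(transcript_ids)) stop("duplicate transcript identifiers")
  if (length(sample_ids) != nrow(values) ||
      length(transcript_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  if (anyNA(values) || any(values < 0) || any(values != round(values)))
    stop("read counts must be non-negative integers")
  storage.mode(values) <- "integer"
  dimnames(values) <- list(sample_ids, transcript_ids)
  class(values) <- c("count_matrix", class(matrix()))
  values
}

#' Transformed expression matrix
#'
#' A real-valued N x K matrix produced by one of the count transformations
#' (or supplied externally), carrying the transform name and its
#' per-transcript parameters.
#'
#' @param values finite numeric matrix (samples x transcripts).
#' @param method name of the transform that produced the values.
#' @param params method-specific parameters (e.g. per-transcript Box-Cox
#'   lambda, pseudo-count).
#' @return an object of class `transformed_matrix`.
#' @export
transformed_matrix <- function(values, method = "none", params = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop("transformed expression values must all be finite")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("sample", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("transcript", seq_len(ncol(values)))
  structure(values, method = method, params = params,
            class = c("transformed_matrix", class(matrix())))
}

#' Minor-allele frequencies of a genotype matrix
#'
#' Allele frequencies are computed as column sums over 2N and folded onto
#' `[0, 0.5]` so that they always refer to the minor allele.
#'
#' @param g a [genotype_matrix()].
#' @return named numeric vector of length M with values in `[0, 0.5]`.
#' @export
maf <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  f <- colSums(unclass(g)) / (2 * nrow(g))
  pmin(f, 1 - f)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix: %d samples x %d markers>\n", nrow(x), ncol(x)))
  cat(sprintf("  MAF range: [%.3f, %.3f]\n", min(maf(x)), max(maf(x))))
  invisible(x)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix: %d samples x %d transcripts>\n",
              nrow(x), ncol(x)))
  cat(sprintf("  mean count: %.1f, zero fraction: %.2f\n",
              mean(x), mean(x == 0)))
  invisible(x)
}

#' @export
print.transformed_matrix <- function(x, ...) {
  cat(sprintf("<transformed_matrix (%s): %d samples x %d transcripts>\n",
              attr(x, "method"), nrow(x), ncol(x)))
  invisible(x)
}

# strip the container class for internal numeric work
raw_values <- function(x) {
  x <- unclass(x)
  attr(x, "method") <- NULL
  attr(x, "params") <- NULL
  x
}
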