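#' Load a genotype dosage matrix from TSV or VCF
#'
#' TSV input is a tab-separated table whose header row holds marker
#' identifiers with a leading `sample_id` column, one sample per row and
#' entries in \{0, 1, 2\} (missing entries allowed, see below). VCF input
#' (v4.x) is parsed via the `GT` field of bi-allelic SNV records: the raw
#' dosage is the number of ALT alleles, flipped to a minor-allele count
#' whenever the ALT allele frequency exceeds 0.5. Multi-allelic records are
#' skipped with a warning. Missing genotypes are imputed to the rounded
#' per-marker mean dosage and their count reported.
#'
#' @param path path to the file.
#' @param format `"tsv"` or `"vcf"`.
#' @return a [genotype_matrix()].
#' @export
load_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") load_genotypes_tsv(path) else load_genotypes_vcf(path)
}

load_genotypes_tsv <- function(path) {
  tab <- read_matrix_tsv(path)
  vals <- tab$values
  bad <- !(vals %in% c(0, 1, 2)) & !is.na(vals)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "genotype entry outside {0, 1, 2} at sample '%s', marker '%s'",
      tab$row_ids[idx[1]], tab$col_ids[idx[2]]))
  }
  vals <- impute_missing_dosages(vals)
  genotype_matrix(vals, tab$row_ids, tab$col_ids)
}

load_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    warning(sprintf("skipping %d multi-allelic VCF record(s)", sum(multi)))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  if (nrow(gt) == 0) stop("no bi-allelic records in VCF: ", path)
  marker_ids <- fix[, "ID"]
  no_id <- is.na(marker_ids) | marker_ids == "." | marker_ids == ""
  marker_ids[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  # ALT allele count per genotype string; tolerate '/' and '|' separators
  dose <- apply(gt, c(1, 2), function(s) {
    if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_real_)
    alleles <- strsplit(s, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles != "0")
  })
  # markers x samples -> samples x markers
  vals <- t(dose)
  colnames(vals) <- marker_ids
  # flip to minor-allele dosage where ALT is the major allele
  alt_freq <- colMeans(vals, na.rm = TRUE) / 2
  flip <- !is.na(alt_freq) & alt_freq > 0.5
  vals[, flip] <- 2 - vals[, flip]
  vals <- impute_missing_dosages(vals)
  genotype_matrix(vals, rownames(vals), marker_ids)
}

impute_missing_dosages <- function(vals) {
  n_missing <- sum(is.na(vals))
  if (n_missing > 0) {
    message(sprintf(
      "imputed %d missing genotype(s) to the rounded per-marker mean dosage",
      n_missing))
    for (j in which(colSums(is.na(vals)) > 0)) {
      m <- mean(vals[, j], na.rm = TRUE)
      if (is.nan(m)) m <- 0
      vals[is.na(vals[, j]), j] <- round(m)
    }
  }
  vals
}

#' Load a read-count matrix from TSV
#'
#' Expects a tab-separated table with a transcript-identifier header row, a
#' leading `sample_id` column and non-negative integer entries.
#'
#' @param path path to the TSV file.
#' @return a [count_matrix()].
#' @export
load_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read_matrix_tsv(path)
  vals <- tab$values
  if (anyNA(vals)) stop("missing values are not allowed in count matrices")
  if (any(vals < 0) || any(vals != round(vals))) {
    idx <- which(vals < 0 | vals != round(vals), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "count entry must be a non-negative integer (sample '%s', transcript '%s')",
      tab$row_ids[idx[1]], tab$col_ids[idx[2]]))
  }
  count_matrix(vals, tab$row_ids, tab$col_ids)
}

# shared TSV matrix reader: header of column ids led by 'sample_id',
# one row per sample
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("malformed matrix file (need header + rows): ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  ncol_expected <- length(header)
  body <- fields[-1]
  nf <- lengths(body)
  if (any(nf != ncol_expected)) {
    bad <- which(nf != ncol_expected)[1] + 1L
    stop(sprintf("malformed matrix file: line %d has %d fields, expected %d",
                 bad, nf[bad - 1L], ncol_expected))
  }
  row_ids <- vapply(body, `[[`, character(1), 1L)
  cells <- matrix(unlist(lapply(body, function(f) f[-1])),
                  nrow = length(body), ncol = ncol_expected - 1L,
                  byrow = TRUE)
  vals <- matrix(suppressWarnings(as.numeric(cells)),
                 nrow = nrow(cells), ncol = ncol(cells))
  vals[cells %in% c("", "NA", ".")] <- NA_real_
  unparsed <- is.na(vals) & !(cells %in% c("", "NA", "."))
  if (any(unparsed)) {
    bad <- which(rowSums(unparsed) > 0)[1] + 1L
    stop(sprintf("malformed matrix file: non-numeric entry on line %d", bad))
  }
  list(values = vals, row_ids = row_ids, col_ids = header[-1])
}

write_matrix_tsv <- function(values, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("sample_id", colnames(values)), collapse = "\t"), con)
  body <- apply(values, 1, paste, collapse = "\t")
  writeLines(paste(rownames(values), body, sep = "\t"), con)
  invisible(path)
}

#' Write a genotype or count matrix as TSV
#'
#' Samples are rows; the header holds marker/transcript identifiers with a
#' leading `sample_id` cell. Loading the file back reproduces values and
#' identifiers exactly.
#'
#' @param x a [genotype_matrix()] or [count_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  write_matrix_tsv(raw_values(x), path)
}

#' Filter markers by minor-allele frequency
#'
#' Retains markers whose MAF is strictly greater than `min_maf`, preserving
#' marker order.
#'
#' @param g a [genotype_matrix()].
#' @param min_maf MAF threshold in `[0, 0.5)`; default 0.05.
#' @return the filtered [genotype_matrix()].
#' @export
filter_markers <- function(g, min_maf = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"),
            min_maf >= 0, min_maf < 0.5)
  keep <- maf(g) > min_maf
  if (!any(keep))
    stop("no markers left after MAF filtering (all MAF <= ", min_maf, ")")
  genotype_matrix(raw_values(g)[, keep, drop = FALSE],
                  rownames(g), colnames(g)[keep])
}

#' Filter transcripts by mean read count
#'
#' Removes transcripts whose mean count across samples is strictly below
#' `min_mean`.
#'
#' @param z a [count_matrix()].
#' @param min_mean minimum mean count; default 10.
#' @return the filtered [count_matrix()].
#' @export
filter_transcripts <- function(z, min_mean = 10) {
  stopifnot(inherits(z, "count_matrix"), min_mean >= 0)
  keep <- colMeans(raw_values(z)) >= min_mean
  if (!any(keep))
    stop("no transcripts left after mean-count filtering (all means < ",
         min_mean, ")")
  count_matrix(raw_values(z)[, keep, drop = FALSE],
               rownames(z), colnames(z)[keep])
}

#' Write association calls and run metadata
#'
#' Summarizes the retained posterior draws of the coefficient matrix into a
#' per-pair table (posterior median, central credible interval, call flag)
#' and persists it as a TSV together with a JSON file of run metadata
#' (model, transform, MCMC settings, seed, filter settings).
#'
#' @param fit an `eqtl_fit` object (see [fit_normal()] and friends).
#' @param path output TSV path; the JSON metadata is written alongside with
#'   extension `.json`.
#' @param credible_level central credible-interval mass (default 0.95).
#' @param full if `TRUE` write all marker-transcript pairs, otherwise only
#'   the called ones.
#' @param call_threshold robust-SD multiplier passed to
#'   [call_associations()].
#' @return the association [tibble::tibble()], invisibly.
#' @export
write_associations <- function(fit, path, credible_level = 0.95,
                               full = FALSE, call_threshold = 2.5) {
  stopifnot(inherits(fit, "eqtl_fit"))
  if (dim(fit$beta_draws)[1] < 2)
    stop("need at least 2 retained posterior draws to summarize")
  tab <- association_table(fit, credible_level = credible_level,
                           call_threshold = call_threshold)
  out <- if (full) tab else dplyr::filter(tab, .data$called)
  utils::write.table(
    data.frame(marker_id = out$marker_id, transcript_id = out$transcript_id,
               beta_median = out$beta_median, beta_lo = out$beta_lo,
               beta_hi = out$beta_hi, called = out$called),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(model = fit$model, transform = fit$transform,
               iterations = fit$mcmc$iterations, burnin = fit$mcmc$burnin,
               seed = fit$mcmc$seed, credible_level = credible_level,
               call_threshold = call_threshold,
               n_markers = length(fit$marker_ids),
               n_transcripts = length(fit$transcript_ids),
               n_called = sum(tab$called),
               filters = fit$filters)
  jsonlite::write_json(meta, paste0(sub("\\.tsv$", "", path), ".json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(out)
}

#' Posterior association table of a fit
#'
#' @inheritParams write_associations
#' @return a tibble with one row per marker-transcript pair: posterior
#'   median, central credible bounds at `credible_level` and the `called`
#'   flag from [call_associations()].
#' @export
association_table <- function(fit, credible_level = 0.95,
                              call_threshold = 2.5) {
  stopifnot(inherits(fit, "eqtl_fit"),
            credible_level > 0, credible_level < 1)
  draws <- fit$beta_draws # draws x M x K
  probs <- c((1 - credible_level) / 2, 0.5, 1 - (1 - credible_level) / 2)
  qs <- apply(draws, c(2, 3), stats::quantile, probs = probs, names = FALSE)
  called <- call_associations(draws, threshold_sd = call_threshold)
  tibble::tibble(
    marker_id = rep(fit$marker_ids, times = length(fit$transcript_ids)),
    transcript_id = rep(fit$transcript_ids, each = length(fit$marker_ids)),
    beta_median = as.vector(qs[2, , ]),
    beta_lo = as.vector(qs[1, , ]),
    beta_hi = as.vector(qs[3, , ]),
    called = as.vector(called))
}
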