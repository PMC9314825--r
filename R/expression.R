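#' Reads-per-million normalisation
#'
#' Scales a genes x samples count matrix to reads per million mapped reads:
#' `rpm = count * 1e6 / library_size`. Column sums of the result equal 1e6
#' whenever the library sizes are the column sums of the counts.
#'
#' @param counts genes x samples matrix (or data frame) of mapped-read
#'   counts, all `>= 0`.
#' @param library_sizes per-sample totals of mapped reads; defaults to
#'   `colSums(counts)`. Must be strictly positive.
#' @return RPM matrix with the input dimnames.
#' @export
rpm_normalize <- function(counts, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE)) abort("counts must be >= 0")
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  if (length(library_sizes) != ncol(counts)) {
    abort("library_sizes must have one entry per sample")
  }
  if (any(library_sizes <= 0)) abort("library sizes must be > 0")
  sweep(counts, 2, library_sizes, "/") * 1e6
}

#' Keep genes expressed above a minimum level
#'
#' Retains genes with abundance strictly greater than `min_rpm` in at least
#' `min_samples` samples; a gene at exactly 10 RPM in 5 samples is removed
#' at the defaults.
#'
#' @param rpm genes x samples RPM matrix.
#' @param min_rpm abundance threshold (default 10).
#' @param min_samples minimum number of samples above it (default 5).
#' @return The filtered matrix.
#' @export
filter_expressed <- function(rpm, min_rpm = 10, min_samples = 5) {
  rpm <- as.matrix(rpm)
  if (min_rpm < 0 || min_samples < 0) abort("thresholds must be >= 0")
  keep <- rowSums(rpm > min_rpm) >= min_samples
  rpm[keep, , drop = FALSE]
}

#' Log2 transform with pseudocount
#'
#' @param x non-negative matrix or vector (e.g. RPM values).
#' @param pseudocount added before taking logs (default 1, so 0 maps to 0).
#' @return `log2(x + pseudocount)`.
#' @export
log2_transform <- function(x, pseudocount = 1) {
  if (any(x < 0, na.rm = TRUE)) abort("values must be >= 0")
  log2(x + pseudocount)
}

#' Post-filter a differential-expression table
#'
#' Keeps genes that are significant (adjusted p below `alpha`), highly
#' expressed (base mean strictly above `min_base_mean`) and strongly
#' changed (absolute log2 fold change strictly above `min_abs_l2fc`); the
#' fold-change criterion is sign-agnostic, so down-regulated genes pass
#' too. Rows with a missing adjusted p value are dropped.
#'
#' @param de_table tibble with columns `gene`, `base_mean`, `log2fc`,
#'   `padj`.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param min_base_mean base-mean cutoff (default 500).
#' @param min_abs_l2fc absolute log2-fold-change cutoff (default 1).
#' @return The filtered tibble.
#' @export
de_postfilter <- function(de_table, alpha = 0.05, min_base_mean = 500, min_abs_l2fc = 1) {
  de_table <- tibble::as_tibble(de_table)
  need <- c("gene", "base_mean", "log2fc", "padj")
  miss <- setdiff(need, names(de_table))
  if (length(miss) > 0) abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  dplyr::filter(
    de_table,
    !is.na(.data$padj), .data$padj < alpha,
    .data$base_mean > min_base_mean,
    abs(.data$log2fc) > min_abs_l2fc
  )
}
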