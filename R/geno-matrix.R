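#' Genotype matrix container
#'
#' A `geno_matrix` holds diploid genotype calls for a panel of samples at a
#' set of biallelic or multi-allelic sites, together with the per-call
#' annotations (genotype quality, read depth) that the call-level filters
#' operate on, and a plain-text log of every filtering step applied.
#'
#' Internally the object stores two allele-index matrices (`allele1`,
#' `allele2`, sites in rows, samples in columns; `NA` encodes a missing
#' call), matching `gq` and `dp` matrices, a site table and a sample table.
#' Allele indices follow the VCF convention: 0 is the reference allele,
#' 1, 2, ... the alternate alleles.
#'
#' @param sites tibble with columns `chrom`, `pos`, `id`, `ref`, `alt`
#'   (comma-separated alternate alleles, `"."` if none), `qual`, `is_indel`.
#' @param samples tibble with columns `sample_id`, `role` (one of
#'   `"hybrid_candidate"`, `"candidate_parent"`, `"reference_panel"`),
#'   `group` and `mother_id`.
#' @param allele1,allele2 integer matrices of allele indices, `NA` = missing.
#' @param gq,dp numeric matrices of per-call genotype quality and depth.
#' @param log character vector of filter-log lines.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(sites, samples, allele1, allele2,
                        gq = NULL, dp = NULL, log = character()) {
  sites <- tibble::as_tibble(sites)
  samples <- tibble::as_tibble(samples)
  validate_sample_sheet(samples, require_all = FALSE)
  ns <- nrow(sites)
  np <- nrow(samples)
  dims_ok <- function(m) is.matrix(m) && nrow(m) == ns && ncol(m) == np
  allele1 <- as_allele_matrix(allele1, ns, np)
  allele2 <- as_allele_matrix(allele2, ns, np)
  if (!dims_ok(allele1) || !dims_ok(allele2)) {
    abort("allele matrices must be sites x samples")
  }
  if (is.null(gq)) gq <- matrix(NA_real_, ns, np)
  if (is.null(dp)) dp <- matrix(NA_real_, ns, np)
  if (!dims_ok(gq) || !dims_ok(dp)) abort("gq/dp matrices must be sites x samples")
  # a half-missing call is treated as fully missing
  half <- is.na(allele1) != is.na(allele2)
  if (any(half)) {
    allele1[half] <- NA_integer_
    allele2[half] <- NA_integer_
  }
  dn <- list(site_key(sites), samples$sample_id)
  dimnames(allele1) <- dn
  dimnames(allele2) <- dn
  dimnames(gq) <- dn
  dimnames(dp) <- dn
  structure(
    list(sites = sites, samples = samples,
         allele1 = allele1, allele2 = allele2,
         gq = gq, dp = dp, log = log),
    class = "geno_matrix"
  )
}

as_allele_matrix <- function(m, ns, np) {
  if (is.null(m)) m <- matrix(NA_integer_, ns, np)
  storage.mode(m) <- "integer"
  m
}

site_key <- function(sites) {
  if (nrow(sites) == 0) return(character())
  paste0(sites$chrom, ":", sites$pos)
}

#' Validate a sample sheet
#'
#' Checks the `sample_id`/`role`/`group` columns, the role vocabulary, and
#' that every hybrid candidate has a known mother.
#'
#' @param samples data frame of sample metadata.
#' @param require_all require at least one hybrid and one candidate parent.
#' @return The sheet as a tibble (invisibly usable in pipes).
#' @export
validate_sample_sheet <- function(samples, require_all = FALSE) {
  samples <- tibble::as_tibble(samples)
  needed <- c("sample_id", "role", "group")
  miss <- setdiff(needed, names(samples))
  if (length(miss) > 0) {
    abort(paste0("sample sheet is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"mother_id" %in% names(samples)) samples$mother_id <- NA_character_
  bad_role <- setdiff(unique(samples$role), .roles)
  if (length(bad_role) > 0) {
    abort(paste0("unknown role(s) in sample sheet: ", paste(bad_role, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) abort("duplicated sample_id in sample sheet")
  if (any(is.na(samples$group) | samples$group == "")) {
    abort("every sample needs a group label")
  }
  hyb <- samples$role == "hybrid_candidate"
  if (any(hyb & (is.na(samples$mother_id) | samples$mother_id == ""))) {
    abort("every hybrid_candidate needs a mother_id")
  }
  if (require_all) {
    if (!any(hyb)) abort("sample sheet contains no hybrid_candidate")
    if (!any(samples$role == "candidate_parent")) {
      abort("sample sheet contains no candidate_parent")
    }
  }
  samples
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d sites x %d samples\n", n_sites(x), n_samples(x)))
  roles <- table(x$samples$role)
  cat("  samples:", paste(sprintf("%s=%d", names(roles), roles), collapse = ", "), "\n")
  if (length(x$log) > 0) {
    cat("  filter log:\n")
    for (l in x$log) cat("    ", l, "\n", sep = "")
  }
  invisible(x)
}

#' Number of sites / samples in a genotype matrix
#' @param gm a [geno_matrix()].
#' @return Integer count.
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' @rdname n_sites
#' @export
n_samples <- function(gm) nrow(gm$samples)

#' Filter log of a genotype matrix
#' @param gm a [geno_matrix()].
#' @return Character vector of log lines, one per filter applied.
#' @export
geno_log <- function(gm) gm$log

is_missing_call <- function(gm) is.na(gm$allele1)

append_log <- function(gm, line) {
  gm$log <- c(gm$log, line)
  gm
}

subset_sites <- function(gm, keep) {
  gm$sites <- gm$sites[keep, , drop = FALSE]
  gm$allele1 <- gm$allele1[keep, , drop = FALSE]
  gm$allele2 <- gm$allele2[keep, , drop = FALSE]
  gm$gq <- gm$gq[keep, , drop = FALSE]
  gm$dp <- gm$dp[keep, , drop = FALSE]
  gm
}

sample_index <- function(gm, ids) {
  idx <- match(ids, gm$samples$sample_id)
  if (anyNA(idx)) {
    abort(paste0("sample(s) not in genotype matrix: ",
                 paste(ids[is.na(idx)], collapse = ", ")))
  }
  idx
}

#' Allele strings for a site
#'
#' @param gm a [geno_matrix()].
#' @param site site row index.
#' @return Character vector of alleles, position 1 = allele index 0 (REF).
#' @export
site_alleles <- function(gm, site) {
  alt <- gm$sites$alt[site]
  if (is.na(alt) || alt == ".") return(gm$sites$ref[site])
  c(gm$sites$ref[site], strsplit(alt, ",", fixed = TRUE)[[1]])
}

#' Tidy a genotype matrix into long form
#'
#' Returns one row per site x sample call, suitable for dplyr/ggplot2 work.
#'
#' @param x a [geno_matrix()].
#' @param ... unused.
#' @return A tibble with columns `chrom`, `pos`, `sample_id`, `allele1`,
#'   `allele2`, `gq`, `dp` and `missing`.
#' @export
tidy.geno_matrix <- function(x, ...) {
  ns <- n_sites(x)
  np <- n_samples(x)
  tibble::tibble(
    chrom = rep(x$sites$chrom, times = np),
    pos = rep(x$sites$pos, times = np),
    sample_id = rep(x$samples$sample_id, each = ns),
    allele1 = as.vector(x$allele1),
    allele2 = as.vector(x$allele2),
    gq = as.vector(x$gq),
    dp = as.vector(x$dp),
    missing = as.vector(is.na(x$allele1))
  )
}

# row-wise min/max across two allele matrices, ignoring NA
row_allele_range <- function(a1, a2) {
  lo <- rep(NA_integer_, nrow(a1))
  hi <- rep(NA_integer_, nrow(a1))
  for (j in seq_len(ncol(a1))) {
    lo <- pmin(lo, a1[, j], a2[, j], na.rm = TRUE)
    hi <- pmax(hi, a1[, j], a2[, j], na.rm = TRUE)
  }
  list(lo = lo, hi = hi)
}
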