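#' Mask low-confidence genotype calls
#'
#' Sets individual genotype calls to missing when their genotype quality or
#' read depth falls below threshold. Thresholds are strict: a call with
#' quality 29 is masked at `min_quality = 30`, a call with quality exactly
#' 30 is kept; likewise depth 2 is masked at `min_depth = 3` and depth 3
#' kept. Sites are never removed here (see [filter_sites()] for site-level
#' removal); masking increases per-site missingness instead.
#'
#' If the matrix carries no per-sample GQ annotation at all, the site-level
#' QUAL is used for every call of that site (with a single warning). If it
#' carries no per-sample DP, the depth criterion is skipped (with a
#' warning). A call whose individual annotation is absent while others are
#' present is retained, since it cannot be judged.
#'
#' @param gm a [geno_matrix()].
#' @param min_quality minimum phred-scaled genotype quality (default 30).
#' @param min_depth minimum read depth in reads (default 3).
#' @return The matrix with failing calls set to missing and a log entry
#'   appended.
#' @export
filter_calls <- function(gm, min_quality = 30, min_depth = 3) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (min_quality < 0 || min_depth < 0) abort("thresholds must be >= 0")

  q <- gm$gq
  if (n_sites(gm) > 0 && all(is.na(q))) {
    warn("no per-sample GQ annotation; falling back to site-level QUAL")
    q <- matrix(gm$sites$qual, n_sites(gm), n_samples(gm))
  }
  d <- gm$dp
  skip_depth <- n_sites(gm) > 0 && all(is.na(d))
  if (skip_depth) warn("no per-sample DP annotation; depth criterion skipped")

  called <- !is_missing_call(gm)
  fail <- (!is.na(q) & q < min_quality)
  if (!skip_depth) fail <- fail | (!is.na(d) & d < min_depth)
  fail <- fail & called

  gm$allele1[fail] <- NA_integer_
  gm$allele2[fail] <- NA_integer_
  append_log(gm, sprintf("filter_calls(min_quality=%s, min_depth=%s): masked %d of %d calls",
                         format(min_quality), format(min_depth),
                         sum(fail), sum(called)))
}

#' Remove indels and high-missingness sites
#'
#' Drops indel sites and sites whose fraction of missing calls (counted
#' after any call-level masking) exceeds `max_missing_fraction`. The bound
#' is strict, "more than": with 10 samples, 1 missing call (10%) is
#' retained and 2 (20%) removed at the default cap of 0.10. Site order is
#' preserved.
#'
#' @param gm a [geno_matrix()].
#' @param max_missing_fraction maximum tolerated fraction of missing calls
#'   per site, in `[0, 1]` (default 0.10).
#' @param drop_indels remove sites whose alleles are not all single bases
#'   (default `TRUE`).
#' @return The filtered matrix, with one log line per criterion in the form
#'   `"name: before -> after"`.
#' @export
filter_sites <- function(gm, max_missing_fraction = 0.10, drop_indels = TRUE) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (max_missing_fraction < 0 || max_missing_fraction > 1) {
    abort("max_missing_fraction must be in [0, 1]")
  }

  before <- n_sites(gm)
  if (drop_indels) {
    gm <- subset_sites(gm, !gm$sites$is_indel)
    gm <- append_log(gm, sprintf("indels: %d -> %d", before, n_sites(gm)))
  }

  before2 <- n_sites(gm)
  if (n_samples(gm) > 0 && before2 > 0) {
    miss_frac <- rowMeans(is_missing_call(gm))
    gm <- subset_sites(gm, miss_frac <= max_missing_fraction)
  }
  append_log(gm, sprintf("missingness(max=%s): %d -> %d",
                         format(max_missing_fraction), before2, n_sites(gm)))
}
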