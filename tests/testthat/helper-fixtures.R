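# In-code fixtures and independent brute-force oracles. The oracles are
# deliberately naive (per-site loops over the definitions) so they share no
# code path with the vectorised implementations they check.

make_test_gm <- function(a1, a2, role, group, mother = NA_character_,
                         ids = NULL, ref = NULL, alt = NULL,
                         gq = 99, dp = 30, qual = 999) {
  a1 <- as.matrix(a1)
  a2 <- as.matrix(a2)
  ns <- nrow(a1)
  np <- ncol(a1)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(np))
  if (is.null(ref)) ref <- rep("A", ns)
  if (is.null(alt)) {
    mx <- suppressWarnings(apply(cbind(a1, a2), 1, max, na.rm = TRUE))
    mx[!is.finite(mx)] <- 1
    alt <- vapply(pmax(mx, 1), function(k) paste(c("C", "G", "T")[seq_len(k)], collapse = ","),
                  character(1))
  }
  sites <- tibble::tibble(chrom = "1", pos = seq_len(ns) * 10L, id = ".",
                          ref = ref, alt = alt, qual = qual, is_indel = FALSE)
  samples <- tibble::tibble(sample_id = ids,
                            role = rep_len(role, np),
                            group = rep_len(group, np),
                            mother_id = rep_len(mother, np))
  geno_matrix(sites, samples, a1, a2,
              gq = matrix(gq, ns, np), dp = matrix(dp, ns, np))
}

# plain bisection, the independent root oracle for the compensation point
oracle_bisection <- function(f, lo, hi, iters = 200) {
  stopifnot(f(lo) <= 0, f(hi) >= 0)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) <= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# exhaustive per-site check of the diagnostic-SNP definition
oracle_diagnostic <- function(gm, max_group_missing = 0.25) {
  panel <- which(gm$samples$role != "hybrid_candidate")
  groups <- sort(unique(gm$samples$group[panel]))
  res <- list()
  for (s in seq_len(n_sites(gm))) {
    ok <- TRUE
    for (g in groups) {
      jg <- panel[gm$samples$group[panel] == g]
      called <- !is.na(gm$allele1[s, jg])
      if (mean(!called) > max_group_missing || !any(called)) ok <- FALSE
    }
    if (!ok) next
    als <- unique(stats::na.omit(c(gm$allele1[s, panel], gm$allele2[s, panel])))
    for (k in als) {
      for (g in groups) {
        jg <- panel[gm$samples$group[panel] == g]
        jo <- setdiff(panel, jg)
        carries <- function(j) {
          !is.na(gm$allele1[s, j]) &&
            (gm$allele1[s, j] == k || gm$allele2[s, j] == k)
        }
        called_g <- jg[!is.na(gm$allele1[s, jg])]
        all_in <- length(called_g) > 0 && all(vapply(called_g, carries, logical(1)))
        none_out <- !any(vapply(jo, carries, logical(1)))
        if (all_in && none_out) {
          res[[length(res) + 1L]] <- data.frame(site = s, group = g, allele = k)
        }
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(site = integer(), group = character(), allele = integer()))
  }
  out <- do.call(rbind, res)
  out[order(out$site, out$group), , drop = FALSE]
}

# naive singleton scan for one candidate
oracle_singleton_sites <- function(gm, cand_id) {
  j <- match(cand_id, gm$samples$sample_id)
  g <- gm$samples$group[j]
  comp <- setdiff(which(gm$samples$role != "hybrid_candidate" & gm$samples$group == g), j)
  out <- integer()
  for (s in seq_len(n_sites(gm))) {
    if (is.na(gm$allele1[s, j]) || gm$allele1[s, j] != gm$allele2[s, j]) next
    dup <- FALSE
    for (cc in comp) {
      if (!is.na(gm$allele1[s, cc]) &&
          gm$allele1[s, cc] == gm$allele1[s, j] &&
          gm$allele2[s, cc] == gm$allele2[s, j]) dup <- TRUE
    }
    if (!dup) out <- c(out, s)
  }
  out
}

# naive informative-site scan
oracle_informative_sites <- function(gm) {
  hyb <- which(gm$samples$role == "hybrid_candidate")
  par <- which(gm$samples$role == "candidate_parent")
  out <- integer()
  for (s in seq_len(n_sites(gm))) {
    a <- gm$allele1[s, ]
    b <- gm$allele2[s, ]
    called <- !is.na(a)
    if (!any(called[hyb]) || !any(called[par])) next
    if (length(unique(stats::na.omit(c(a, b)))) < 2) next
    if (any(called[hyb] & a[hyb] == b[hyb])) next
    if (any(called[par] & a[par] != b[par])) next
    out <- c(out, s)
  }
  out
}

# the typing chain as run on a study cohort; returns per-hybrid results
run_typing_chain <- function(gm, min_consistency = 0.9, min_margin = 0.2) {
  flt <- filter_sites(filter_calls(gm), 0.10)
  inf <- select_informative_sites(flt)
  diag <- find_group_diagnostic_snps(inf)
  ct <- classify_cross_types(inf, diag, min_consistency = min_consistency)
  fathers <- gm$samples$sample_id[gm$samples$group == "C4" &
                                    gm$samples$role == "candidate_parent"]
  sing <- find_parent_singletons(inf, fathers)
  asg <- assign_pollen_parents(inf, sing, min_margin = min_margin)
  list(cross = ct, assign = asg, informative = inf, diag = diag, singletons = sing)
}
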