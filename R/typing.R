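#' Retain F1-informative sites
#'
#' An F1 between two homozygous (or strongly divergent) parents is
#' heterozygous wherever the parents carry fixed differences. This filter
#' keeps the sites usable for hybrid typing: sites that are polymorphic
#' among the retained samples, where every hybrid candidate with a
#' non-missing call is heterozygous and every candidate parent with a
#' non-missing call is homozygous, with at least one non-missing call in
#' each role. Individuals with missing calls do not veto a site.
#'
#' @param gm a [geno_matrix()] whose sample sheet contains at least one
#'   `hybrid_candidate` and one `candidate_parent`.
#' @return The matrix restricted to informative sites (site order kept).
#' @export
select_informative_sites <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  hyb <- gm$samples$role == "hybrid_candidate"
  par <- gm$samples$role == "candidate_parent"
  if (!any(hyb)) abort("no hybrid_candidate samples in the matrix")
  if (!any(par)) abort("no candidate_parent samples in the matrix")

  a1 <- gm$allele1
  a2 <- gm$allele2
  called <- !is.na(a1)
  het <- called & (a1 != a2)

  n_called_hyb <- rowSums(called[, hyb, drop = FALSE])
  n_called_par <- rowSums(called[, par, drop = FALSE])
  any_hom_hyb <- rowSums(called[, hyb, drop = FALSE] & !het[, hyb, drop = FALSE]) > 0
  any_het_par <- rowSums(het[, par, drop = FALSE]) > 0

  rng <- row_allele_range(a1, a2)
  polymorphic <- !is.na(rng$lo) & rng$hi > rng$lo

  keep <- polymorphic & n_called_hyb > 0 & n_called_par > 0 & !any_hom_hyb & !any_het_par
  before <- n_sites(gm)
  gm <- subset_sites(gm, keep)
  append_log(gm, sprintf("informative: %d -> %d", before, n_sites(gm)))
}

#' Discover group-diagnostic SNPs
#'
#' A diagnostic SNP for a photosynthetic group is a site carrying an allele
#' present (in at least one copy) in every non-missing individual of that
#' group and in no non-missing individual of any other group. Only
#' non-hybrid samples (candidate parents and the reference panel) are
#' consulted. Sites with more than `max_group_missing` missing data within
#' any group are excluded before testing; the bound is strict ("more
#' than").
#'
#' @param gm a [geno_matrix()].
#' @param groups group labels to consider; default, every group present
#'   among the non-hybrid samples. Each must have at least one sample.
#' @param max_group_missing within-group missingness cap (default 0.25).
#' @return A `diag_snp_set`: list with `entries` (tibble of `site`,
#'   `chrom`, `pos`, `group`, `allele`, `allele_str`) and
#'   `per_group_counts`. Use [tidy()] to get the entries table.
#' @export
find_group_diagnostic_snps <- function(gm, groups = NULL, max_group_missing = 0.25) {
  stopifnot(inherits(gm, "geno_matrix"))
  panel <- gm$samples$role != "hybrid_candidate"
  if (is.null(groups)) groups <- sort(unique(gm$samples$group[panel]))
  if (length(groups) < 2) abort("need at least 2 groups to call diagnostic SNPs")
  cols <- lapply(groups, function(g) which(panel & gm$samples$group == g))
  empty <- groups[lengths(cols) == 0]
  if (length(empty) > 0) {
    abort(paste0("group(s) with zero non-hybrid samples: ", paste(empty, collapse = ", ")))
  }
  panel_cols <- unlist(cols)

  ns <- n_sites(gm)
  entries <- tibble::tibble(site = integer(), chrom = character(), pos = integer(),
                            group = character(), allele = integer(),
                            allele_str = character())
  if (ns == 0) {
    return(new_diag_snp_set(entries, groups, max_group_missing))
  }

  a1 <- gm$allele1
  a2 <- gm$allele2
  called <- !is.na(a1)
  n_called <- lapply(cols, function(j) rowSums(called[, j, drop = FALSE]))
  miss_ok <- Reduce(`&`, lapply(seq_along(cols), function(i) {
    frac <- 1 - n_called[[i]] / length(cols[[i]])
    frac <= max_group_missing & n_called[[i]] > 0
  }))

  max_allele <- suppressWarnings(max(a1[, panel_cols], a2[, panel_cols], na.rm = TRUE))
  if (!is.finite(max_allele)) max_allele <- -1L
  out <- list()
  for (k in 0:max_allele) {
    carries <- called & (a1 == k | a2 == k)
    n_carry <- lapply(cols, function(j) rowSums(carries[, j, drop = FALSE]))
    tot_carry <- Reduce(`+`, n_carry)
    for (i in seq_along(groups)) {
      hit <- miss_ok &
        n_carry[[i]] == n_called[[i]] &
        tot_carry - n_carry[[i]] == 0
      if (any(hit)) {
        w <- unname(which(hit))
        out[[length(out) + 1L]] <- tibble::tibble(
          site = w, chrom = gm$sites$chrom[w], pos = gm$sites$pos[w],
          group = groups[i], allele = k,
          allele_str = vapply(w, function(s) site_alleles(gm, s)[k + 1L], character(1))
        )
      }
    }
  }
  if (length(out) > 0) entries <- dplyr::arrange(dplyr::bind_rows(out), .data$site, .data$group)
  new_diag_snp_set(entries, groups, max_group_missing)
}

new_diag_snp_set <- function(entries, groups, max_group_missing) {
  counts <- table(factor(entries$group, levels = groups))
  structure(list(entries = entries,
                 per_group_counts = setNames(as.integer(counts), names(counts)),
                 groups = groups,
                 max_group_missing = max_group_missing),
            class = "diag_snp_set")
}

#' @export
print.diag_snp_set <- function(x, ...) {
  cat(sprintf("<diag_snp_set> %d entries at %d sites\n",
              nrow(x$entries), length(unique(x$entries$site))))
  for (g in names(x$per_group_counts)) {
    cat(sprintf("  %s: %d diagnostic alleles\n", g, x$per_group_counts[[g]]))
  }
  invisible(x)
}

#' @rdname find_group_diagnostic_snps
#' @param x a `diag_snp_set`.
#' @param ... unused.
#' @export
tidy.diag_snp_set <- function(x, ...) x$entries

#' Classify the cross type of a hybrid
#'
#' Tests, at every diagnostic site, whether the hybrid carries exactly one
#' allele diagnostic of each parental group of a candidate cross. The
#' paternal group is fixed (C4 by default); one hypothesis is evaluated per
#' non-paternal group with diagnostic alleles (e.g. C3 x C4 and C3+C4 x
#' C4). A site tests a hypothesis only when it carries diagnostic alleles
#' for both sides of that cross; it is consistent when the hybrid carries
#' exactly one copy of each such allele and no copy of diagnostic alleles
#' of groups outside the cross. The hypothesis whose consistency reaches `min_consistency`
#' wins; if both (or neither) pass the verdict is `"ambiguous"`
#' (`"not_F1"`); a hybrid with no testable site is `"untestable"`.
#'
#' @param gm a [geno_matrix()] containing the hybrid and its mother.
#' @param hybrid_id sample id of the hybrid candidate.
#' @param diag a `diag_snp_set` from [find_group_diagnostic_snps()].
#' @param min_consistency fraction of tested sites that must be consistent
#'   (default 0.9, tolerating low-level genotyping error).
#' @param paternal_group label of the pollen-parent group (default `"C4"`).
#' @return A one-row tibble: `hybrid_id`, `mother_id`, `mother_group`,
#'   `hypothesis` (the verdict), `sites_tested`, `sites_consistent`,
#'   `consistency`. The per-hypothesis table is attached as attribute
#'   `"hypotheses"`.
#' @export
classify_cross_type <- function(gm, hybrid_id, diag, min_consistency = 0.9,
                                paternal_group = .paternal_group) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(diag, "diag_snp_set"))
  if (nrow(diag$entries) == 0) abort("diagnostic SNP set is empty")
  h <- sample_index(gm, hybrid_id)
  if (gm$samples$role[h] != "hybrid_candidate") {
    abort(paste0(hybrid_id, " is not a hybrid_candidate"))
  }
  mother_id <- gm$samples$mother_id[h]
  m <- match(mother_id, gm$samples$sample_id)
  if (is.na(m)) abort(paste0("mother ", mother_id, " of ", hybrid_id, " not in matrix"))
  mother_group <- gm$samples$group[m]

  ent <- diag$entries
  # match entries to current site order by coordinates, so the set survives
  # subsetting of the matrix it was derived from
  site_now <- match(paste0(ent$chrom, ":", ent$pos), site_key(gm$sites))
  ent <- ent[!is.na(site_now), , drop = FALSE]
  site_now <- site_now[!is.na(site_now)]
  if (nrow(ent) == 0) {
    return(tibble::tibble(hybrid_id = hybrid_id, mother_id = mother_id,
                          mother_group = mother_group, hypothesis = "untestable",
                          sites_tested = 0L, sites_consistent = 0L,
                          consistency = NA_real_))
  }
  ha1 <- gm$allele1[site_now, h]
  ha2 <- gm$allele2[site_now, h]
  copies <- (!is.na(ha1)) * ((ha1 == ent$allele) + (ha2 == ent$allele))

  maternal_candidates <- setdiff(unique(ent$group), paternal_group)
  if (length(maternal_candidates) == 0) {
    abort("diagnostic set has no non-paternal group")
  }

  tested_entry <- !is.na(ha1)
  hyp <- purrr::map_dfr(maternal_candidates, function(g) {
    want <- ifelse(ent$group %in% c(g, paternal_group), 1L, 0L)
    ok_entry <- copies == want
    # a site can only test the hypothesis "g x paternal" when it carries a
    # diagnostic allele for each side of the cross
    two_sided <- tapply(ent$group == g, ent$site, any) &
      tapply(ent$group == paternal_group, ent$site, any)
    by_site <- tapply(ok_entry & tested_entry, ent$site, all) &
      tapply(tested_entry, ent$site, all) & two_sided
    tested_site <- tapply(tested_entry, ent$site, all) & two_sided
    tibble::tibble(
      hypothesis = paste0(g, "x", paternal_group),
      maternal_group = g,
      sites_tested = sum(tested_site),
      sites_consistent = sum(by_site[tested_site]),
      consistency = ifelse(sum(tested_site) > 0,
                           sum(by_site[tested_site]) / sum(tested_site), NA_real_)
    )
  })

  passing <- which(!is.na(hyp$consistency) & hyp$consistency >= min_consistency)
  total_tested <- max(hyp$sites_tested)
  verdict <- if (total_tested == 0) {
    "untestable"
  } else if (length(passing) == 1) {
    hyp$hypothesis[passing]
  } else if (length(passing) > 1) {
    "ambiguous"
  } else {
    "not_F1"
  }
  report_row <- if (length(passing) == 1) passing else {
    match(mother_group, hyp$maternal_group, nomatch = 1L)
  }

  out <- tibble::tibble(
    hybrid_id = hybrid_id,
    mother_id = mother_id,
    mother_group = mother_group,
    hypothesis = verdict,
    sites_tested = hyp$sites_tested[report_row],
    sites_consistent = hyp$sites_consistent[report_row],
    consistency = hyp$consistency[report_row]
  )
  attr(out, "hypotheses") <- hyp
  out
}

#' @rdname classify_cross_type
#' @return `classify_cross_types()` stacks the one-row results for every
#'   hybrid candidate in the matrix.
#' @export
classify_cross_types <- function(gm, diag, min_consistency = 0.9,
                                 paternal_group = .paternal_group) {
  ids <- gm$samples$sample_id[gm$samples$role == "hybrid_candidate"]
  if (length(ids) == 0) abort("no hybrid_candidate samples in the matrix")
  purrr::map_dfr(ids, function(id) {
    classify_cross_type(gm, id, diag, min_consistency, paternal_group)
  })
}

#' Find paternity-informative singletons of candidate parents
#'
#' A singleton is a homozygous genotype unique to a single individual among
#' all non-hybrid individuals of the same photosynthetic group. Because an
#' F1 receives one paternal allele, a hybrid carrying a candidate's
#' singleton allele supports that candidate's paternity.
#'
#' @param gm a [geno_matrix()].
#' @param candidate_ids candidates to scan; default, every sample with role
#'   `candidate_parent`. All must have that role.
#' @return A tibble of class `singleton_sets` with columns `owner_id`,
#'   `site`, `chrom`, `pos`, `allele`, `allele_str`; one row per singleton.
#' @export
find_parent_singletons <- function(gm, candidate_ids = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (is.null(candidate_ids)) {
    candidate_ids <- gm$samples$sample_id[gm$samples$role == "candidate_parent"]
  }
  if (length(candidate_ids) == 0) abort("no candidate parents to scan")
  idx <- sample_index(gm, candidate_ids)
  not_parent <- gm$samples$role[idx] != "candidate_parent"
  if (any(not_parent)) {
    abort(paste0("not candidate_parent: ",
                 paste(candidate_ids[not_parent], collapse = ", ")))
  }

  a1 <- gm$allele1
  a2 <- gm$allele2
  non_hybrid <- gm$samples$role != "hybrid_candidate"
  out <- purrr::map(seq_along(candidate_ids), function(i) {
    j <- idx[i]
    grp <- gm$samples$group[j]
    comp <- which(non_hybrid & gm$samples$group == grp)
    comp <- setdiff(comp, j)
    hom <- !is.na(a1[, j]) & a1[, j] == a2[, j]
    if (length(comp) > 0) {
      same <- matrix(FALSE, n_sites(gm), length(comp))
      for (ci in seq_along(comp)) {
        cc <- comp[ci]
        same[, ci] <- !is.na(a1[, cc]) & a1[, cc] == a1[, j] & a2[, cc] == a2[, j]
      }
      unique_hom <- hom & rowSums(same) == 0
    } else {
      unique_hom <- hom
    }
    w <- unname(which(unique_hom))
    tibble::tibble(
      owner_id = candidate_ids[i], site = w,
      chrom = gm$sites$chrom[w], pos = gm$sites$pos[w],
      allele = a1[w, j],
      allele_str = vapply(w, function(s) {
        al <- site_alleles(gm, s)
        if (a1[s, j] + 1L <= length(al)) al[a1[s, j] + 1L] else NA_character_
      }, character(1))
    )
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("singleton_sets", class(res))
  res
}

#' Singleton counts per candidate parent
#' @param singletons a `singleton_sets` tibble from [find_parent_singletons()].
#' @return Tibble `owner_id`, `n_singletons`.
#' @export
singleton_counts <- function(singletons) {
  dplyr::count(tibble::as_tibble(singletons), .data$owner_id, name = "n_singletons")
}

#' Assign the pollen parent of a hybrid by singleton matching
#'
#' For each candidate, counts the singleton sites at which the hybrid has a
#' non-missing call (tested) and carries at least one copy of the
#' candidate's singleton allele (positive match). Candidates are ranked by
#' match fraction; the top candidate is assigned when its fraction exceeds
#' the runner-up's by at least `min_margin`, otherwise the verdict is
#' `"ambiguous"` (e.g. two indistinguishable accessions of one lineage).
#' With a single testable candidate the verdict is `"degenerate"`; with no
#' testable site at all, `"untestable"`.
#'
#' @param gm a [geno_matrix()].
#' @param hybrid_id sample id of the hybrid.
#' @param singletons a `singleton_sets` tibble from [find_parent_singletons()].
#' @param min_margin minimum lead in match fraction for an assignment
#'   (default 0.2).
#' @return An `assignment_report`; [tidy()] gives the ranked candidate
#'   table, [glance()] a one-row summary.
#' @export
assign_pollen_parent <- function(gm, hybrid_id, singletons, min_margin = 0.2) {
  stopifnot(inherits(gm, "geno_matrix"))
  h <- sample_index(gm, hybrid_id)
  sing <- tibble::as_tibble(singletons)
  if (nrow(sing) == 0) abort("empty singleton set")

  site_now <- match(paste0(sing$chrom, ":", sing$pos), site_key(gm$sites))
  sing <- sing[!is.na(site_now), , drop = FALSE]
  site_now <- site_now[!is.na(site_now)]
  ha1 <- gm$allele1[site_now, h]
  ha2 <- gm$allele2[site_now, h]
  tested <- !is.na(ha1)
  match_pos <- tested & (ha1 == sing$allele | ha2 == sing$allele)

  cand <- sing |>
    dplyr::mutate(tested = tested, match = match_pos) |>
    dplyr::group_by(.data$owner_id) |>
    dplyr::summarise(singletons_tested = sum(.data$tested),
                     positive_matches = sum(.data$match), .groups = "drop") |>
    dplyr::mutate(
      hybrid_id = hybrid_id,
      match_fraction = ifelse(.data$singletons_tested > 0,
                              .data$positive_matches / .data$singletons_tested,
                              NA_real_)
    ) |>
    dplyr::relocate("hybrid_id") |>
    dplyr::rename(candidate_id = "owner_id") |>
    dplyr::arrange(dplyr::desc(.data$match_fraction), .data$candidate_id)

  testable <- which(!is.na(cand$match_fraction))
  if (length(testable) == 0) {
    verdict <- "untestable"
    assigned <- NA_character_
    margin <- NA_real_
  } else if (length(testable) == 1) {
    verdict <- "degenerate"
    assigned <- cand$candidate_id[testable]
    margin <- NA_real_
  } else {
    margin <- cand$match_fraction[1] - cand$match_fraction[2]
    if (margin >= min_margin) {
      verdict <- "assigned"
      assigned <- cand$candidate_id[1]
    } else {
      verdict <- "ambiguous"
      assigned <- NA_character_
    }
  }

  structure(list(hybrid_id = hybrid_id, candidates = cand,
                 assigned_parent = assigned, margin = margin,
                 verdict = verdict, min_margin = min_margin),
            class = "assignment_report")
}

#' @export
print.assignment_report <- function(x, ...) {
  cat(sprintf("<assignment_report> hybrid %s: %s", x$hybrid_id, x$verdict))
  if (!is.na(x$assigned_parent)) {
    cat(sprintf(" -> %s (margin %.3f)", x$assigned_parent,
                ifelse(is.na(x$margin), NA, x$margin)))
  }
  cat("\n")
  print(x$candidates)
  invisible(x)
}

#' @rdname assign_pollen_parent
#' @param x an `assignment_report`.
#' @param ... unused.
#' @export
tidy.assignment_report <- function(x, ...) x$candidates

#' @rdname assign_pollen_parent
#' @export
glance.assignment_report <- function(x, ...) {
  top <- x$candidates[1, ]
  tibble::tibble(
    hybrid_id = x$hybrid_id,
    assigned_parent = x$assigned_parent,
    verdict = x$verdict,
    margin = x$margin,
    top_candidate = top$candidate_id,
    top_match_fraction = top$match_fraction,
    top_tested = top$singletons_tested,
    top_matches = top$positive_matches
  )
}

#' @rdname assign_pollen_parent
#' @return `assign_pollen_parents()` returns one [glance()] row per hybrid
#'   candidate in the matrix.
#' @export
assign_pollen_parents <- function(gm, singletons, min_margin = 0.2) {
  ids <- gm$samples$sample_id[gm$samples$role == "hybrid_candidate"]
  if (length(ids) == 0) abort("no hybrid_candidate samples in the matrix")
  purrr::map_dfr(ids, function(id) {
    glance(assign_pollen_parent(gm, id, singletons, min_margin))
  })
}
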