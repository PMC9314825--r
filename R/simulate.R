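# Synthetic-data generators. Every generator is seed-deterministic and
# returns its ground truth alongside the data, so the whole inference chain
# can be verified by recovery tests. The genotype generator emulates the
# divergence structure the typing pipeline relies on: deeply divergent
# lineage groups with tri-group fixed differences (diagnostic SNPs) and
# individual-private homozygous alleles (paternity singletons), plus shared
# polymorphism and monomorphic background. Sites are unlinked.

#' Configuration of a synthetic lineage panel
#'
#' @param n_groups number of lineage groups (default 3).
#' @param group_labels labels, default `c("C3", "C3+C4", "C4")`.
#' @param individuals_per_group panel individuals per group, scalar or one
#'   per group (default 4).
#' @param n_sites total number of sites (default 15000, the scale of an
#'   RNA-seq-derived informative-site panel).
#' @param site_class_proportions named proportions over the four site
#'   classes `shared_polymorphic`, `group_diagnostic`, `individual_private`
#'   and `monomorphic`; must sum to 1. The defaults plant about 120
#'   diagnostic sites and about 300 private sites per panel individual.
#' @param seed integer seed.
#' @return A `panel_config` list.
#' @export
panel_config <- function(n_groups = 3,
                         group_labels = c("C3", "C3+C4", "C4"),
                         individuals_per_group = 4,
                         n_sites = 15000,
                         site_class_proportions = c(shared_polymorphic = 0.552,
                                                    group_diagnostic = 0.008,
                                                    individual_private = 0.24,
                                                    monomorphic = 0.2),
                         seed = NULL) {
  if (length(group_labels) != n_groups) abort("need one label per group")
  sizes <- if (length(individuals_per_group) == 1) {
    rep(individuals_per_group, n_groups)
  } else individuals_per_group
  if (length(sizes) != n_groups || any(sizes < 1)) {
    abort("individuals_per_group must be positive, one per group")
  }
  classes <- c("shared_polymorphic", "group_diagnostic", "individual_private", "monomorphic")
  p <- site_class_proportions[classes]
  if (anyNA(p) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    abort("site_class_proportions must be named, non-negative and sum to 1")
  }
  if (n_sites < 0) abort("n_sites must be >= 0")
  counts <- largest_remainder(p * n_sites, n_sites)
  names(counts) <- classes
  if (counts[["group_diagnostic"]] > 0 && (n_groups < 2 || any(sizes < 2))) {
    abort("diagnostic sites need >= 2 groups with >= 2 individuals each")
  }
  if (counts[["individual_private"]] > 0 && any(sizes < 3)) {
    abort("private sites need >= 3 individuals per group (uniqueness would be ambiguous)")
  }
  structure(list(n_groups = n_groups, group_labels = group_labels,
                 sizes = sizes, n_sites = n_sites, class_counts = counts,
                 seed = seed),
            class = "panel_config")
}

largest_remainder <- function(x, total) {
  f <- floor(x)
  rem <- total - sum(f)
  if (rem > 0) {
    ord <- order(x - f, decreasing = TRUE)
    f[ord[seq_len(rem)]] <- f[ord[seq_len(rem)]] + 1
  }
  as.integer(f)
}

#' Simulate a divergent-lineage genotype panel
#'
#' Generates clean (noise-free, complete) diploid genotypes for the
#' configured panel. Site classes: *group-diagnostic* sites are fixed
#' multi-group differences (group `j` homozygous for allele `j`), so each
#' group's allele is carried by all of its members and by nobody else;
#' *individual-private* sites give one individual a homozygous private
#' allele (allele 2) while its own group is fixed for allele 1 and the
#' other groups for allele 0 — the configuration that stays F1-informative
#' in multi-father cohorts while marking exactly one candidate;
#' *shared-polymorphic* sites segregate at a common frequency drawn from
#' U(0.1, 0.9) in every group, rejection-resampled so no shared site
#' accidentally satisfies the diagnostic or singleton definition;
#' *monomorphic* sites are invariant. Ownership of private sites cycles
#' through all panel individuals.
#'
#' @param cfg a [panel_config()].
#' @return `list(gm, truth)`: the clean [geno_matrix()] and a
#'   `synthetic_truth` list with the planted site classes, diagnostic
#'   entries and private (singleton) entries.
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "panel_config"))
  run <- function() simulate_panel_impl(cfg)
  if (!is.null(cfg$seed)) withr::with_seed(cfg$seed, run()) else run()
}

simulate_panel_impl <- function(cfg) {
  labels <- cfg$group_labels
  sizes <- cfg$sizes
  n_ind <- sum(sizes)
  group_of <- rep(labels, sizes)
  ids <- unlist(lapply(seq_along(labels), function(g) {
    sprintf("%s_%d", gsub("[^A-Za-z0-9]", "", labels[g]), seq_len(sizes[g]))
  }))
  samples <- tibble::tibble(sample_id = ids, role = "candidate_parent",
                            group = group_of, mother_id = NA_character_)

  ns <- cfg$n_sites
  cls <- sample(rep(names(cfg$class_counts), cfg$class_counts))
  a1 <- matrix(0L, ns, n_ind)
  a2 <- matrix(0L, ns, n_ind)
  group_cols <- lapply(labels, function(g) which(group_of == g))

  # diagnostic: group j fixed for allele j
  w_diag <- which(cls == "group_diagnostic")
  for (g in seq_along(labels)) {
    a1[w_diag, group_cols[[g]]] <- g - 1L
    a2[w_diag, group_cols[[g]]] <- g - 1L
  }

  # private: owner hom allele 2, own group allele 1, other groups allele 0
  w_priv <- which(cls == "individual_private")
  owners <- if (length(w_priv) > 0) rep_len(seq_len(n_ind), length(w_priv)) else integer()
  if (length(w_priv) > 0) {
    for (g in seq_along(labels)) {
      rows <- w_priv[group_of[owners] == labels[g]]
      a1[rows, group_cols[[g]]] <- 1L
      a2[rows, group_cols[[g]]] <- 1L
    }
    a1[cbind(w_priv, owners)] <- 2L
    a2[cbind(w_priv, owners)] <- 2L
  }

  # shared polymorphism, rejection-resampled against accidental diagnostic
  # or singleton configurations
  w_shared <- which(cls == "shared_polymorphic")
  if (length(w_shared) > 0) {
    p <- runif(length(w_shared), 0.1, 0.9)
    s1 <- matrix(rbinom(length(w_shared) * n_ind, 1L, p), length(w_shared), n_ind)
    s2 <- matrix(rbinom(length(w_shared) * n_ind, 1L, p), length(w_shared), n_ind)
    bad <- shared_site_violations(s1, s2, group_cols)
    iter <- 0
    while (any(bad) && iter < 100) {
      nb <- sum(bad)
      s1[bad, ] <- rbinom(nb * n_ind, 1L, p[bad])
      s2[bad, ] <- rbinom(nb * n_ind, 1L, p[bad])
      bad <- shared_site_violations(s1, s2, group_cols)
      iter <- iter + 1
    }
    if (any(bad)) {  # deterministic fallback: everyone heterozygous
      s1[bad, ] <- 0L
      s2[bad, ] <- 1L
    }
    a1[w_shared, ] <- s1
    a2[w_shared, ] <- s2
  }

  n_alt <- ifelse(cls == "group_diagnostic", max(cfg$n_groups - 1L, 1L),
                  ifelse(cls == "individual_private", 2L, 1L))
  allele_strs <- draw_allele_strings(ns, n_alt)
  sites <- tibble::tibble(
    chrom = "1", pos = seq_len(ns) * 10L, id = ".",
    ref = allele_strs$ref, alt = allele_strs$alt,
    qual = 999, is_indel = FALSE
  )

  gm <- geno_matrix(sites, samples, a1, a2,
                    gq = matrix(99, ns, n_ind), dp = matrix(30, ns, n_ind))

  diagnostic_entries <- if (length(w_diag) > 0) {
    tidyr::expand_grid(site = w_diag, g = seq_along(labels)) |>
      dplyr::mutate(pos = gm$sites$pos[.data$site], chrom = "1",
                    group = labels[.data$g], allele = .data$g - 1L) |>
      dplyr::select("site", "chrom", "pos", "group", "allele")
  } else {
    tibble::tibble(site = integer(), chrom = character(), pos = integer(),
                   group = character(), allele = integer())
  }
  private_entries <- tibble::tibble(
    site = w_priv, chrom = rep("1", length(w_priv)), pos = gm$sites$pos[w_priv],
    owner_id = ids[owners], allele = rep(2L, length(w_priv))
  )
  truth <- structure(list(
    config = cfg,
    site_classes = tibble::tibble(site = seq_len(ns), pos = sites$pos, class = cls),
    diagnostic_entries = diagnostic_entries,
    private_entries = private_entries,
    pedigree = tibble::tibble(hybrid = character(), mother = character(),
                              father = character(), cross = character())
  ), class = "synthetic_truth")
  list(gm = gm, truth = truth)
}

# a shared site is invalid if any group holds a homozygous genotype seen in
# exactly one of its members (an accidental singleton), or if either allele
# is fixed in one group and absent from every other (accidentally
# diagnostic)
shared_site_violations <- function(s1, s2, group_cols) {
  nr <- nrow(s1)
  viol <- rep(FALSE, nr)
  carried0 <- s1 == 0L | s2 == 0L
  carried1 <- s1 == 1L | s2 == 1L
  hom0 <- s1 == 0L & s2 == 0L
  hom1 <- s1 == 1L & s2 == 1L
  all0 <- matrix(0L, nr, length(group_cols))
  all1 <- matrix(0L, nr, length(group_cols))
  for (g in seq_along(group_cols)) {
    j <- group_cols[[g]]
    viol <- viol |
      rowSums(hom0[, j, drop = FALSE]) == 1L |
      rowSums(hom1[, j, drop = FALSE]) == 1L
    all0[, g] <- rowSums(carried0[, j, drop = FALSE]) == length(j)
    all1[, g] <- rowSums(carried1[, j, drop = FALSE]) == length(j)
  }
  if (length(group_cols) >= 2) {
    for (g in seq_along(group_cols)) {
      others <- unlist(group_cols[-g])
      viol <- viol |
        (all0[, g] == 1L & rowSums(carried0[, others, drop = FALSE]) == 0L) |
        (all1[, g] == 1L & rowSums(carried1[, others, drop = FALSE]) == 0L)
    }
  }
  viol
}

draw_allele_strings <- function(ns, n_alt) {
  bases <- c("A", "C", "G", "T")
  ref <- character(ns)
  alt <- character(ns)
  if (ns == 0) return(list(ref = ref, alt = alt))
  picks <- matrix(0L, ns, 3)
  for (i in seq_len(ns)) picks[i, ] <- sample.int(4, 3)
  ref <- bases[picks[, 1]]
  alt <- ifelse(n_alt >= 2,
                paste(bases[picks[, 2]], bases[picks[, 3]], sep = ","),
                bases[picks[, 2]])
  list(ref = ref, alt = alt)
}

#' Simulate an F1 cross
#'
#' Appends `n_offspring` F1 individuals to the matrix. Each offspring
#' receives one uniformly drawn allele from each parent at every site,
#' independently across sites (no linkage). Offspring are annotated with
#' role `hybrid_candidate`, the known `mother_id`, and a `father_id` truth
#' column used only by recovery tests, never by the typing chain. Sites
#' where a parent call is missing yield missing offspring calls.
#'
#' @param gm a [geno_matrix()] containing both parents.
#' @param mother_id,father_id parent sample ids (equal ids simulate
#'   self-pollination).
#' @param n_offspring number of F1s (default 1).
#' @param seed integer seed.
#' @param prefix offspring id prefix (default `"<mother>x<father>_F1"`).
#' @return The extended matrix.
#' @export
simulate_cross <- function(gm, mother_id, father_id, n_offspring = 1,
                           seed = NULL, prefix = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  mi <- sample_index(gm, mother_id)
  fi <- sample_index(gm, father_id)
  if (is.null(prefix)) prefix <- paste0(mother_id, "x", father_id, "_F1")
  run <- function() {
    ns <- n_sites(gm)
    kids_a1 <- matrix(NA_integer_, ns, n_offspring)
    kids_a2 <- matrix(NA_integer_, ns, n_offspring)
    for (k in seq_len(n_offspring)) {
      pick_m <- runif(ns) < 0.5
      pick_f <- runif(ns) < 0.5
      from_m <- ifelse(pick_m, gm$allele1[, mi], gm$allele2[, mi])
      from_f <- ifelse(pick_f, gm$allele1[, fi], gm$allele2[, fi])
      kids_a1[, k] <- pmin(from_m, from_f)
      kids_a2[, k] <- pmax(from_m, from_f)
    }
    ids <- sprintf("%s_%d", prefix, seq_len(n_offspring))
    if (any(ids %in% gm$samples$sample_id)) abort("offspring ids collide with existing samples")
    cross <- paste0(gm$samples$group[mi], "x", gm$samples$group[fi])
    kid_samples <- tibble::tibble(sample_id = ids, role = "hybrid_candidate",
                                  group = cross, mother_id = mother_id,
                                  father_id = father_id)
    samples <- dplyr::bind_rows(gm$samples, kid_samples)
    pad <- function(m, fill) cbind(m, matrix(fill, ns, n_offspring))
    geno_matrix(gm$sites, samples,
                cbind(gm$allele1, kids_a1), cbind(gm$allele2, kids_a2),
                gq = pad(gm$gq, 99), dp = pad(gm$dp, 30), log = gm$log)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

#' Observation-noise configuration
#'
#' @param mean_depth mean per-call read depth (reads; default 20).
#' @param depth_dispersion negative-binomial size parameter; smaller means
#'   more overdispersed depth (default 5).
#' @param genotype_error_rate probability a non-missing call is replaced by
#'   a different genotype of the site's alleles (default 0.01).
#' @param missing_rate probability a call is dropped entirely (default 0.1).
#' @param quality_model function mapping depth to a phred-like genotype
#'   quality; default `pmin(99, 4 * depth)`.
#' @param seed integer seed.
#' @return An `obs_config` list.
#' @export
obs_config <- function(mean_depth = 20, depth_dispersion = 5,
                       genotype_error_rate = 0.01, missing_rate = 0.1,
                       quality_model = NULL, seed = NULL) {
  if (mean_depth <= 0) abort("mean_depth must be > 0")
  for (p in c(genotype_error_rate, missing_rate)) {
    if (p < 0 || p > 1) abort("rates must be probabilities in [0, 1]")
  }
  if (is.null(quality_model)) quality_model <- function(depth) pmin(99, 4 * depth)
  structure(list(mean_depth = mean_depth, depth_dispersion = depth_dispersion,
                 genotype_error_rate = genotype_error_rate,
                 missing_rate = missing_rate, quality_model = quality_model,
                 seed = seed),
            class = "obs_config")
}

#' Apply an RNA-seq-like observation layer to clean genotypes
#'
#' Draws a negative-binomial read depth per call, assigns genotype quality
#' from depth via the configured quality model, replaces genotypes with a
#' random different genotype at the configured error rate, and drops calls
#' at the configured missingness rate.
#'
#' @param gm a clean [geno_matrix()].
#' @param cfg an [obs_config()].
#' @return The matrix with noisy calls and updated `dp`/`gq`.
#' @export
apply_observation_model <- function(gm, cfg) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(cfg, "obs_config"))
  run <- function() {
    ns <- n_sites(gm)
    np <- n_samples(gm)
    n <- ns * np
    if (n == 0) return(gm)
    dp <- matrix(rnbinom(n, size = cfg$depth_dispersion, mu = cfg$mean_depth), ns, np)
    gq <- matrix(cfg$quality_model(as.vector(dp)), ns, np)
    dimnames(dp) <- dimnames(gm$dp)
    dimnames(gq) <- dimnames(gm$gq)
    gm$dp <- dp
    gm$gq <- gq

    called <- !is_missing_call(gm)
    if (cfg$genotype_error_rate > 0) {
      err <- called & matrix(runif(n) < cfg$genotype_error_rate, ns, np)
      idx <- which(err, arr.ind = TRUE)
      if (nrow(idx) > 0) {
        n_alleles <- 1L + ifelse(gm$sites$alt == ".", 0L,
                                 vapply(strsplit(gm$sites$alt, ",", fixed = TRUE),
                                        length, integer(1)))
        for (r in seq_len(nrow(idx))) {
          s <- idx[r, 1]; j <- idx[r, 2]
          na <- max(n_alleles[s], 2L)
          pairs <- genotype_pairs(na)
          cur <- which(pairs[, 1] == gm$allele1[s, j] & pairs[, 2] == gm$allele2[s, j])
          choices <- setdiff(seq_len(nrow(pairs)), cur)
          pick <- pairs[sample(choices, 1), ]
          gm$allele1[s, j] <- pick[1]
          gm$allele2[s, j] <- pick[2]
        }
      }
    }
    if (cfg$missing_rate > 0) {
      drop <- matrix(runif(n) < cfg$missing_rate, ns, np)
      gm$allele1[drop] <- NA_integer_
      gm$allele2[drop] <- NA_integer_
    }
    append_log(gm, sprintf(
      "observation_model(depth=%g, error=%g, missing=%g)",
      cfg$mean_depth, cfg$genotype_error_rate, cfg$missing_rate))
  }
  if (!is.null(cfg$seed)) withr::with_seed(cfg$seed, run()) else run()
}

genotype_pairs <- function(n_alleles) {
  al <- 0:(n_alleles - 1L)
  m <- expand.grid(a = al, b = al)
  m <- m[m$a <= m$b, , drop = FALSE]
  as.matrix(m)
}

#' Simulate a full hybrid study cohort
#'
#' Convenience wrapper reproducing the design of an F1 parentage study:
#' a clean lineage panel, F1 crosses with mothers drawn from the non-C4
#' groups and pollen parents from the C4 group, and an observation layer.
#' The true pedigree is returned for recovery checks.
#'
#' @param cfg a [panel_config()] (its `seed` is ignored in favour of
#'   `seed`).
#' @param n_crosses named integer vector: number of F1s per maternal group
#'   (default `c("C3" = 14, "C3+C4" = 6)`, one offspring per cross).
#' @param obs an [obs_config()] for the observation layer, or `NULL` for
#'   clean output.
#' @param seed integer seed driving panel, crosses and observation noise.
#' @return `list(gm, truth)`; `truth$pedigree` holds hybrid/mother/father.
#' @export
simulate_study <- function(cfg = panel_config(),
                           n_crosses = c("C3" = 14, "C3+C4" = 6),
                           obs = obs_config(),
                           seed = 1) {
  cfg$seed <- seed
  sim <- simulate_panel(cfg)
  gm <- sim$gm
  truth <- sim$truth
  paternal <- .paternal_group
  fathers_pool <- gm$samples$sample_id[gm$samples$group == paternal]
  if (length(fathers_pool) == 0) abort("panel has no C4 group to draw fathers from")

  ped <- withr::with_seed(seed + 1, {
    purrr::imap_dfr(n_crosses, function(nk, mg) {
      pool <- gm$samples$sample_id[gm$samples$group == mg]
      if (length(pool) == 0) abort(paste0("panel has no group ", mg))
      tibble::tibble(mother = sample(pool, nk, replace = TRUE),
                     father = sample(fathers_pool, nk, replace = TRUE),
                     cross = paste0(mg, "x", paternal))
    })
  })
  ped$hybrid <- sprintf("H%02d", seq_len(nrow(ped)))
  for (i in seq_len(nrow(ped))) {
    gm <- simulate_cross(gm, ped$mother[i], ped$father[i], 1,
                         seed = seed + 100 + i, prefix = ped$hybrid[i])
  }
  # simulate_cross appends "_1" to the prefix
  ped$hybrid <- paste0(ped$hybrid, "_1")
  if (!is.null(obs)) {
    obs$seed <- seed + 999
    gm <- apply_observation_model(gm, obs)
  }
  truth$pedigree <- ped[, c("hybrid", "mother", "father", "cross")]
  list(gm = gm, truth = truth)
}

#' Simulate a gas-exchange cohort
#'
#' Generates A/Ci curves at the standard 14-step reference-CO2 sequence
#' (400, 250, 150, 120, 100, 85, 70, 50, 35, 400, 600, 800, 1000, 1200
#' umol mol-1, including the return-to-400 step) from nonrectangular-
#' hyperbola parameters drawn per individual, with Gaussian noise on A.
#' Group physiology is calibrated through the CO2 compensation point: each
#' individual's CCP is drawn uniformly from its group's band (C3 43.5-47.5,
#' C3+C4 5-15, C4 2-9 umol mol-1) and the respiratory offset is derived
#' from it, so C3-like curves compensate near 45 umol mol-1 and C4-like
#' ones below 10. Stomatal conductance is calibrated so C4 intrinsic
#' water-use efficiency sits about 38% above the non-C4 groups.
#'
#' @param group_params tibble of per-group parameter distributions (see
#'   `default_aci_params()`); default, the calibration above.
#' @param n_per_group curves per group, recycled across groups (default 5).
#' @param noise_sd Gaussian noise on A, umol m-2 s-1 (default 0.5).
#' @param seed integer seed.
#' @return `list(curves, truth)`: observations (one row per logged step)
#'   and the drawn true parameters per individual. Intercellular CO2 is
#'   solved self-consistently from the stomatal drawdown
#'   `ci = reference - 1.6 a / gs`.
#' @export
simulate_aci_cohort <- function(group_params = default_aci_params(),
                                n_per_group = 5, noise_sd = 0.5, seed = NULL) {
  run <- function() {
    seq_ref <- aci_co2_sequence()
    out_curves <- list()
    out_truth <- list()
    n_per <- rep_len(n_per_group, nrow(group_params))
    for (g in seq_len(nrow(group_params))) {
      gp <- group_params[g, ]
      if (n_per[g] == 0) next
      for (i in seq_len(n_per[g])) {
        ce <- max(rnorm(1, gp$ce_mean, gp$ce_sd), 1e-3)
        a_sat <- max(rnorm(1, gp$a_sat_mean, gp$a_sat_sd), 1)
        theta <- clamp(rnorm(1, gp$theta_mean, gp$theta_sd), 0.05, 0.99)
        ccp <- runif(1, gp$ccp_lo, gp$ccp_hi)
        # the respiratory offset that puts the compensation point at ccp
        r_offset <- nrh_assimilation(ccp, ce, a_sat, theta, 0)
        gs <- max(rnorm(1, gp$gs_mean, gp$gs_sd), 0.01)
        id <- sprintf("%s_aci_%d", gsub("[^A-Za-z0-9]", "", gp$group), i)
        ci <- vapply(seq_ref, solve_ci, numeric(1),
                     ce = ce, a_sat = a_sat, theta = theta,
                     r_offset = r_offset, gs = gs)
        a <- nrh_assimilation(ci, ce, a_sat, theta, r_offset) +
          rnorm(length(ci), 0, noise_sd)
        t0 <- 26.3 + rnorm(1, 0, 0.15)
        out_curves[[length(out_curves) + 1L]] <- tibble::tibble(
          individual_id = id, group = gp$group,
          reference_co2 = seq_ref, ci = ci, a_net = a,
          gs = pmax(gs + rnorm(length(ci), 0, 0.003), 0.005),
          t_leaf = t0 + rnorm(length(ci), 0, 0.1)
        )
        a_400 <- nrh_assimilation(solve_ci(400, ce, a_sat, theta, r_offset, gs),
                                  ce, a_sat, theta, r_offset)
        out_truth[[length(out_truth) + 1L]] <- tibble::tibble(
          individual_id = id, group = gp$group,
          ce = ce, a_sat = a_sat, theta = theta, r_offset = r_offset,
          ccp = ccp, gs_400 = gs, a_400 = a_400, iwue = a_400 / gs
        )
      }
    }
    list(curves = dplyr::bind_rows(out_curves), truth = dplyr::bind_rows(out_truth))
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

# intercellular CO2 at a given ambient level: the drawdown across stomata
# is 1.6 * A / gs (1.6 converts water-vapour conductance to CO2), solved
# self-consistently with the assimilation model; below the compensation
# point A < 0 and Ci exceeds ambient, exactly as a gas analyser records
solve_ci <- function(ca, ce, a_sat, theta, r_offset, gs) {
  f <- function(ci) ca - 1.6 * nrh_assimilation(ci, ce, a_sat, theta, r_offset) / gs - ci
  hi <- ca + 1.6 * r_offset / gs + 10
  uniroot(f, c(0, hi), tol = 1e-8)$root
}

#' The canonical 14-step reference-CO2 measurement sequence
#' @return Numeric vector (umol mol-1); step 10 is the return-to-400 point.
#' @export
aci_co2_sequence <- function() {
  c(400, 250, 150, 120, 100, 85, 70, 50, 35, 400, 600, 800, 1000, 1200)
}

#' @rdname simulate_aci_cohort
#' @export
default_aci_params <- function() {
  tibble::tribble(
    ~group,   ~ce_mean, ~ce_sd, ~a_sat_mean, ~a_sat_sd, ~theta_mean, ~theta_sd, ~ccp_lo, ~ccp_hi, ~gs_mean, ~gs_sd,
    "C3",     0.09,     0.004,  25,          1.5,       0.70,        0.04,      43.5,    47.5,    0.170,    0.012,
    "C3+C4",  0.18,     0.010,  30,          2.0,       0.70,        0.04,      5,       15,      0.300,    0.020,
    "C4",     0.45,     0.030,  35,          2.0,       0.75,        0.04,      2,       9,       0.285,    0.020
  )
}

#' Simulate a trait table with planted dominance
#'
#' Parent trait values are drawn from their group distributions; each
#' hybrid's value is `midparent + dominance * (high parent - midparent)`
#' plus Gaussian noise with standard deviation `noise_sd * |mother -
#' father|` (noise scales with the parental difference).
#'
#' @param group_means tibble with columns `trait`, `group`, `mean`, `sd`.
#' @param dominance_per_trait named numeric vector, trait -> planted
#'   dominance (0 = additive, 1 = full high-parent dominance).
#' @param pedigree tibble with columns `hybrid`, `mother`, `father`,
#'   `mother_group`, `father_group`.
#' @param noise_sd relative noise level (default 0).
#' @param seed integer seed.
#' @return `list(traits, truth)`: a trait table covering parents and
#'   hybrids, and the truth (dominance and drawn parent values).
#' @export
simulate_trait_table <- function(group_means, dominance_per_trait, pedigree,
                                 noise_sd = 0, seed = NULL) {
  group_means <- tibble::as_tibble(group_means)
  pedigree <- tibble::as_tibble(pedigree)
  need <- c("hybrid", "mother", "father", "mother_group", "father_group")
  if (!all(need %in% names(pedigree))) {
    abort(paste0("pedigree needs columns ", paste(need, collapse = ", ")))
  }
  run <- function() {
    parents <- dplyr::distinct(dplyr::bind_rows(
      tibble::tibble(accession_id = pedigree$mother, group = pedigree$mother_group),
      tibble::tibble(accession_id = pedigree$father, group = pedigree$father_group)
    ))
    traits <- names(dominance_per_trait)
    parent_vals <- tidyr::expand_grid(parents, trait = traits) |>
      dplyr::left_join(group_means, by = c("group", "trait")) |>
      dplyr::mutate(value = rnorm(dplyr::n(), .data$mean, .data$sd)) |>
      dplyr::select("accession_id", "group", "trait", "value")
    if (anyNA(parent_vals$value)) {
      abort("group_means lacks an entry for some group x trait")
    }
    hyb_vals <- tidyr::expand_grid(pedigree, trait = traits) |>
      dplyr::left_join(dplyr::rename(parent_vals, mother = "accession_id",
                                     mother_value = "value")[, c("mother", "trait", "mother_value")],
                       by = c("mother", "trait")) |>
      dplyr::left_join(dplyr::rename(parent_vals, father = "accession_id",
                                     father_value = "value")[, c("father", "trait", "father_value")],
                       by = c("father", "trait")) |>
      dplyr::mutate(
        dominance = unname(dominance_per_trait[.data$trait]),
        midparent = (.data$mother_value + .data$father_value) / 2,
        high = pmax(.data$mother_value, .data$father_value),
        value = .data$midparent + .data$dominance * (.data$high - .data$midparent) +
          rnorm(dplyr::n(), 0, noise_sd * abs(.data$mother_value - .data$father_value)),
        accession_id = .data$hybrid,
        group = paste0(.data$mother_group, "x", .data$father_group)
      )
    traits_tbl <- dplyr::bind_rows(
      parent_vals,
      hyb_vals[, c("accession_id", "group", "trait", "value")]
    )
    truth <- list(dominance = dominance_per_trait,
                  parent_values = parent_vals,
                  pedigree = pedigree)
    list(traits = traits_tbl, truth = truth)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}
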