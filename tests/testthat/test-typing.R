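# Genotype encoding in these fixtures: allele indices into ref/alt, e.g.
# 0/1 is heterozygous ref/alt.

test_that("informative-site selection keeps the canonical F1 pattern only", {
  # site 1: hybrids het, parents opposite homozygotes -> keep
  # site 2: one hybrid homozygous -> drop
  # site 3: one parent heterozygous -> drop
  # site 4: monomorphic -> drop
  a1 <- rbind(c(0L, 0L, 0L, 1L), c(0L, 0L, 0L, 1L), c(0L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L))
  a2 <- rbind(c(1L, 1L, 0L, 1L), c(1L, 0L, 0L, 1L), c(1L, 1L, 0L, 1L), c(0L, 0L, 0L, 0L))
  gm <- make_test_gm(a1, a2,
                     role = c("hybrid_candidate", "hybrid_candidate",
                              "candidate_parent", "candidate_parent"),
                     group = c("C3xC4", "C3xC4", "C3", "C4"),
                     mother = c("S03", "S03", NA, NA))
  out <- select_informative_sites(gm)
  expect_equal(out$sites$pos, gm$sites$pos[1])
  expect_error(select_informative_sites(make_test_gm(a1, a2, role = "candidate_parent",
                                                     group = "C3")),
               "no hybrid_candidate")
})

test_that("informative sites at zero noise equal the brute-force oracle set", {
  cfg <- panel_config(n_sites = 600, seed = 21)
  sim <- simulate_study(cfg, n_crosses = c("C3" = 3, "C3+C4" = 2), obs = NULL, seed = 21)
  inf <- select_informative_sites(sim$gm)
  expect_equal(inf$sites$pos, sim$gm$sites$pos[oracle_informative_sites(sim$gm)])
  # missing calls do not veto a site
  gm2 <- sim$gm
  gm2$allele1[, 1] <- NA
  gm2$allele2[, 1] <- NA
  inf2 <- select_informative_sites(gm2)
  expect_true(all(inf$sites$pos %in% inf2$sites$pos))
})

test_that("diagnostic SNP discovery honours fixation, exclusivity and the 25% cap", {
  # 2 groups of 2: fixed difference -> diagnostic for both groups
  gm <- make_test_gm(rbind(c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L)),
                     rbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 1L, 1L)),
                     role = "candidate_parent", group = c("G1", "G1", "G2", "G2"))
  d <- find_group_diagnostic_snps(gm)
  e1 <- d$entries[d$entries$site == 1, ]
  expect_setequal(paste(e1$group, e1$allele), c("G1 0", "G2 1"))
  # site 2 (G1 = {0/0, 0/1}, G2 = {1/1, 1/1}): allele 1 is carried inside G1
  # so it is not exclusive to G2; allele 0 is still carried by all of G1 and
  # absent from G2, so only the G1 entry remains
  e2 <- d$entries[d$entries$site == 2, ]
  expect_setequal(paste(e2$group, e2$allele), c("G1 0"))

  # within-group missingness cap is strict ("more than 25%")
  a1 <- matrix(rep(c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L), 2), 2, 8, byrow = TRUE)
  gm2 <- make_test_gm(a1, a1, role = "candidate_parent",
                      group = rep(c("G1", "G2"), each = 4))
  gm2$allele1[1, 1] <- NA; gm2$allele2[1, 1] <- NA      # 25% in G1 -> ok
  gm2$allele1[2, 1:2] <- NA; gm2$allele2[2, 1:2] <- NA  # 50% in G1 -> excluded
  d2 <- find_group_diagnostic_snps(gm2)
  expect_true(1 %in% d2$entries$site)
  expect_false(2 %in% d2$entries$site)

  expect_error(find_group_diagnostic_snps(gm2, groups = c("G1", "G3")), "G3")
})

test_that("planted tri-group fixed differences are recovered exactly (oracle-checked)", {
  for (seed in c(3, 11)) {
    cfg <- panel_config(n_sites = 1000,
                        site_class_proportions = c(shared_polymorphic = 0.66,
                                                   group_diagnostic = 0.04,
                                                   individual_private = 0.2,
                                                   monomorphic = 0.1),
                        seed = seed)
    sim <- simulate_panel(cfg)
    d <- find_group_diagnostic_snps(sim$gm)
    planted <- sim$truth$diagnostic_entries
    expect_equal(nrow(planted), 40 * 3)
    got <- d$entries[, c("site", "group", "allele")]
    expect_equal(dplyr::arrange(got, site, group),
                 dplyr::arrange(planted[, c("site", "group", "allele")], site, group),
                 ignore_attr = TRUE)
    # independent exhaustive check
    orc <- oracle_diagnostic(sim$gm)
    expect_equal(got$site, orc$site)
    expect_equal(got$allele, orc$allele)
    # exclusivity: an allele is never diagnostic for two groups at one site
    expect_equal(anyDuplicated(got[, c("site", "allele")]), 0L)
  }
})

test_that("cross-type classification follows the one-allele-from-each-parent rule", {
  # one site, alleles: 0 diagnostic of C3, 1 of C3+C4, 2 of C4
  a1 <- matrix(c(0L, 0L, 1L, 2L, 0L, 2L), 1)
  a2 <- matrix(c(0L, 0L, 1L, 2L, 2L, 2L), 1)
  gm <- make_test_gm(a1, a2,
                     role = c("candidate_parent", "candidate_parent", "candidate_parent",
                              "candidate_parent", "hybrid_candidate", "hybrid_candidate"),
                     group = c("C3", "C3", "C3+C4", "C4", "C3xC4", "C3xC4"),
                     mother = c(NA, NA, NA, NA, "S01", "S01"))
  d <- find_group_diagnostic_snps(gm)
  ct <- classify_cross_type(gm, "S05", d, min_consistency = 0.9)   # 0/2: C3 + C4
  expect_equal(ct$hypothesis, "C3xC4")
  expect_equal(ct$sites_consistent, 1L)
  ct2 <- classify_cross_type(gm, "S06", d)                         # 2/2: no C3 allele
  expect_equal(ct2$hypothesis, "not_F1")
  # hybrid with no non-missing diagnostic call is untestable, not a pass
  gm$allele1[1, 5] <- NA
  gm$allele2[1, 5] <- NA
  expect_equal(classify_cross_type(gm, "S05", d)$hypothesis, "untestable")
})

test_that("noisy C3+C4 x C4 cohorts are classified with high consistency", {
  # ~114 diagnostic sites, mirroring a realistic diagnostic panel size
  cfg <- panel_config(n_sites = 3000,
                      site_class_proportions = c(shared_polymorphic = 0.48,
                                                 group_diagnostic = 0.038,
                                                 individual_private = 0.24,
                                                 monomorphic = 0.242),
                      seed = 55)
  sim <- simulate_study(cfg, n_crosses = c("C3+C4" = 20),
                        obs = obs_config(genotype_error_rate = 0.01, missing_rate = 0),
                        seed = 55)
  expect_equal(nrow(sim$truth$diagnostic_entries) / 3, 114)
  res <- run_typing_chain(sim$gm)
  expect_true(all(res$cross$hypothesis == "C3+C4xC4"))
  expect_true(all(res$cross$consistency >= 0.95))
})

test_that("singletons are unique homozygous genotypes within a photosynthetic type", {
  # C4 trio: site 1 {G/G, A/A, A/A} -> P1 singleton; site 2 {G/G, G/G, A/A}
  # -> singleton only for P3
  a <- rbind(c(1L, 0L, 0L), c(1L, 1L, 0L))
  gm <- make_test_gm(a, a, role = "candidate_parent", group = "C4",
                     ref = c("A", "A"), alt = c("G", "G"))
  s <- find_parent_singletons(gm)
  # site 1: only P1's G/G is unique (P2 and P3 share A/A);
  # site 2: P1 and P2 share G/G, P3's A/A is unique
  expect_setequal(paste(s$owner_id, s$site), c("S01 1", "S03 2"))
  expect_error(find_parent_singletons(gm, "nope"), "nope")
})

test_that("planted private sites are recovered exactly at zero noise", {
  sim <- simulate_panel(panel_config(n_sites = 2000, seed = 13))
  cands <- sim$gm$samples$sample_id
  s <- find_parent_singletons(sim$gm)
  planted <- sim$truth$private_entries
  for (id in cands) {
    got <- sort(s$site[s$owner_id == id])
    want <- sort(planted$site[planted$owner_id == id])
    expect_equal(got, want)
    expect_equal(got, oracle_singleton_sites(sim$gm, id))
  }
  counts <- singleton_counts(s)
  expect_true(all(counts$n_singletons == nrow(planted) / length(cands)))
})

test_that("paternity assignment ranks by match fraction with a margin rule", {
  # forced outcome: hybrid matches all of P1's singletons, none of P2's
  n <- 40
  a1 <- matrix(0L, n, 4)
  a2 <- matrix(0L, n, 4)
  a1[1:20, 1] <- 1L; a2[1:20, 1] <- 1L      # P1 private hom at sites 1-20
  a1[21:40, 2] <- 1L; a2[21:40, 2] <- 1L    # P2 private hom at sites 21-40
  a2[1:20, 4] <- 1L                          # hybrid carries P1 alleles het
  gm <- make_test_gm(a1, a2,
                     role = c("candidate_parent", "candidate_parent",
                              "candidate_parent", "hybrid_candidate"),
                     group = c("C4", "C4", "C4", "C3xC4"),
                     mother = c(NA, NA, NA, "S03"))
  sing <- find_parent_singletons(gm, c("S01", "S02"))
  rep <- assign_pollen_parent(gm, "S04", sing)
  expect_equal(rep$verdict, "assigned")
  expect_equal(rep$assigned_parent, "S01")
  expect_equal(rep$margin, 1)
  expect_true(all(tidy(rep)$positive_matches <= tidy(rep)$singletons_tested))

  # identical match fractions -> ambiguous (indistinguishable lineages)
  a2[21:40, 4] <- 1L  # hybrid now matches P2's singletons too
  gm2 <- make_test_gm(a1, a2,
                      role = c("candidate_parent", "candidate_parent",
                               "candidate_parent", "hybrid_candidate"),
                      group = c("C4", "C4", "C4", "C3xC4"),
                      mother = c(NA, NA, NA, "S03"))
  sing2 <- find_parent_singletons(gm2, c("S01", "S02"))
  rep2 <- assign_pollen_parent(gm2, "S04", sing2)
  expect_equal(rep2$verdict, "ambiguous")
  expect_true(is.na(rep2$assigned_parent))
  expect_equal(rep2$margin, 0)
})

test_that("true fathers are recovered for 50 noisy F1s across 4 candidates", {
  cfg <- panel_config(n_sites = 4000, seed = 91)
  sim <- simulate_study(cfg, n_crosses = c("C3" = 30, "C3+C4" = 20),
                        obs = obs_config(genotype_error_rate = 0.02, missing_rate = 0.1),
                        seed = 91)
  res <- run_typing_chain(sim$gm)
  rp <- dplyr::left_join(res$assign, sim$truth$pedigree, by = c(hybrid_id = "hybrid"))
  assigned <- rp$verdict == "assigned"
  expect_true(sum(assigned) > 0)
  expect_equal(mean(rp$assigned_parent[assigned] == rp$father[assigned]), 1)
})

test_that("permuting sample order changes no typing result", {
  cfg <- panel_config(n_sites = 800, seed = 61)
  sim <- simulate_study(cfg, n_crosses = c("C3" = 3, "C3+C4" = 2), obs = NULL, seed = 61)
  gm <- sim$gm
  perm <- withr::with_seed(1, sample(n_samples(gm)))
  gmp <- gm
  gmp$samples <- gm$samples[perm, ]
  gmp$allele1 <- gm$allele1[, perm]
  gmp$allele2 <- gm$allele2[, perm]
  gmp$gq <- gm$gq[, perm]
  gmp$dp <- gm$dp[, perm]

  d1 <- find_group_diagnostic_snps(select_informative_sites(gm))
  d2 <- find_group_diagnostic_snps(select_informative_sites(gmp))
  expect_equal(d1$entries, d2$entries)
  ct1 <- dplyr::arrange(classify_cross_types(select_informative_sites(gm), d1), hybrid_id)
  ct2 <- dplyr::arrange(classify_cross_types(select_informative_sites(gmp), d2), hybrid_id)
  expect_equal(ct1, ct2, ignore_attr = TRUE)
  s1 <- find_parent_singletons(gm)
  s2 <- find_parent_singletons(gmp)
  expect_equal(dplyr::arrange(tibble::as_tibble(s1), owner_id, site),
               dplyr::arrange(tibble::as_tibble(s2), owner_id, site))
})
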