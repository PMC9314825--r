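test_that("panel configs are validated and degenerate requests refused", {
  expect_error(panel_config(site_class_proportions = c(shared_polymorphic = 0.5,
                                                       group_diagnostic = 0.1,
                                                       individual_private = 0.1,
                                                       monomorphic = 0.1)),
               "sum to 1")
  # private sites with a single individual are impossible to make unique
  expect_error(panel_config(individuals_per_group = 1,
                            site_class_proportions = c(shared_polymorphic = 0,
                                                       group_diagnostic = 0,
                                                       individual_private = 1,
                                                       monomorphic = 0)),
               "private sites")
  expect_error(panel_config(individuals_per_group = 1), "individuals")
  cfg0 <- panel_config(n_sites = 0, seed = 1)
  sim0 <- simulate_panel(cfg0)
  expect_equal(n_sites(sim0$gm), 0)
  expect_equal(nrow(sim0$truth$site_classes), 0)
})

test_that("an all-diagnostic panel is fully recovered by diagnostic discovery", {
  cfg <- panel_config(n_sites = 100,
                      site_class_proportions = c(shared_polymorphic = 0,
                                                 group_diagnostic = 1,
                                                 individual_private = 0,
                                                 monomorphic = 0),
                      seed = 5)
  sim <- simulate_panel(cfg)
  d <- find_group_diagnostic_snps(sim$gm)
  expect_setequal(unique(d$entries$site), 1:100)
  expect_equal(unname(d$per_group_counts), rep(100L, 3))
})

test_that("panel generation is byte-identical for a fixed seed", {
  cfg <- panel_config(n_sites = 150, seed = 99)
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(simulate_panel(cfg)$gm, f1)
  write_vcf(simulate_panel(cfg)$gm, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("crosses obey Mendelian inheritance", {
  # opposite homozygotes force heterozygous offspring
  gm <- make_test_gm(matrix(c(0L, 1L), 1), matrix(c(0L, 1L), 1),
                     role = "candidate_parent", group = c("C3", "C4"))
  out <- simulate_cross(gm, "S01", "S02", 5, seed = 2)
  kids <- out$samples$sample_id[out$samples$role == "hybrid_candidate"]
  expect_equal(unname(out$allele1[1, kids]), rep(0L, 5))
  expect_equal(unname(out$allele2[1, kids]), rep(1L, 5))
  expect_equal(unique(out$samples$mother_id[out$samples$role == "hybrid_candidate"]), "S01")

  # het x het segregates 1:2:1 across 10,000 sites
  n <- 10000
  gm2 <- make_test_gm(matrix(0L, n, 2), matrix(1L, n, 2),
                      role = "candidate_parent", group = c("C3", "C4"))
  out2 <- simulate_cross(gm2, "S01", "S02", 1, seed = 3)
  kid <- out2$samples$sample_id[out2$samples$role == "hybrid_candidate"]
  g <- out2$allele1[, kid] + out2$allele2[, kid]
  obs <- tabulate(g + 1, 3)
  p <- stats::chisq.test(obs, p = c(0.25, 0.5, 0.25))$p.value
  expect_gt(p, 0.01)

  # selfing cannot decrease homozygosity
  sim <- simulate_panel(panel_config(n_sites = 500, seed = 6))
  self <- simulate_cross(sim$gm, "C3_1", "C3_1", 1, seed = 7)
  kid <- self$samples$sample_id[self$samples$role == "hybrid_candidate"]
  hom_kid <- mean(self$allele1[, kid] == self$allele2[, kid])
  hom_par <- mean(sim$gm$allele1[, "C3_1"] == sim$gm$allele2[, "C3_1"])
  expect_gte(hom_kid, hom_par)

  expect_error(simulate_cross(gm, "S01", "nope", 1, seed = 1), "nope")
})

test_that("the observation model perturbs calls at the configured rates", {
  sim <- simulate_panel(panel_config(n_sites = 900, seed = 8))

  clean <- apply_observation_model(sim$gm, obs_config(genotype_error_rate = 0,
                                                      missing_rate = 0, seed = 9))
  expect_identical(clean$allele1, sim$gm$allele1)
  expect_identical(clean$allele2, sim$gm$allele2)
  expect_false(identical(clean$dp, sim$gm$dp))  # depth/quality re-annotated

  noisy <- apply_observation_model(sim$gm, obs_config(missing_rate = 0.1, seed = 10))
  n <- length(noisy$allele1)
  miss <- mean(is.na(noisy$allele1))
  expect_lt(abs(miss - 0.1), 3 * sqrt(0.1 * 0.9 / n))

  again <- apply_observation_model(sim$gm, obs_config(missing_rate = 0.1, seed = 10))
  expect_identical(again$allele1, noisy$allele1)
  expect_identical(again$dp, noisy$dp)

  # errors change genotypes without touching missingness
  err <- apply_observation_model(sim$gm, obs_config(genotype_error_rate = 0.05,
                                                    missing_rate = 0, seed = 11))
  changed <- mean(err$allele1 != sim$gm$allele1 | err$allele2 != sim$gm$allele2)
  expect_lt(abs(changed - 0.05), 3 * sqrt(0.05 * 0.95 / n))
  expect_false(anyNA(err$allele1))
})

test_that("empty gas-exchange cohorts and zero-noise round-trips behave", {
  sim0 <- simulate_aci_cohort(n_per_group = 0, seed = 1)
  expect_equal(nrow(sim0$curves), 0)
  sim <- simulate_aci_cohort(n_per_group = c(1, 1, 1), noise_sd = 0, seed = 23)
  expect_equal(nrow(sim$curves), 3 * 14)
  expect_equal(unique(sim$curves$reference_co2), unique(aci_co2_sequence()))
  fits <- fit_aci_curves(sim$curves, seed = 23)
  m <- dplyr::inner_join(fits, sim$truth, by = "individual_id", suffix = c("_f", "_t"))
  expect_lt(max(abs(m$ce_f - m$ce_t) / m$ce_t), 1e-5)
})

test_that("the full chain recovers every planted pedigree at benign settings", {
  cfg <- panel_config(n_sites = 3000, seed = 70)
  sim <- simulate_study(cfg, n_crosses = c("C3" = 6, "C3+C4" = 4),
                        obs = obs_config(genotype_error_rate = 0, missing_rate = 0),
                        seed = 70)
  res <- run_typing_chain(sim$gm)
  tr <- sim$truth$pedigree
  ct <- dplyr::left_join(res$cross, tr, by = c(hybrid_id = "hybrid"))
  expect_equal(mean(ct$hypothesis == ct$cross), 1)
  rp <- dplyr::left_join(res$assign, tr, by = c(hybrid_id = "hybrid"))
  expect_true(all(rp$verdict == "assigned"))
  expect_equal(mean(rp$assigned_parent == rp$father), 1)
})
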