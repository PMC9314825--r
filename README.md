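# hybridtyper

F1 hybrid detection and pollen-parent assignment between divergent
photosynthetic lineages (C3, C3+C4, C4), from RNA-seq-derived SNP
genotypes — plus the gas-exchange and expression computations used to
phenotype such hybrids.

## Who this is for

Plant evolutionary biologists and physiologists working with controlled or
suspected crosses between photosynthetic types (the motivating system is
the grass *Alloteropsis semialata*, which contains C3, intermediate C3+C4
and C4 lineages that still hybridise). The mother of each putative hybrid
is known (the plant the seed was collected from); the open questions are
whether the plant is a genuine F1 between types, which type of cross it
is, and which individual provided the pollen.

## The core method

Starting from a multi-sample VCF and a sample sheet of roles
(hybrid candidate / candidate parent / reference panel) and group labels:

1. **Filter genotypes** — mask calls with genotype quality < 30 or depth
   < 3 reads; drop indels and sites with > 10% missing calls (all bounds
   strict).
2. **Informative sites** — keep polymorphic sites where every hybrid is
   heterozygous and every candidate parent homozygous (missing calls do
   not veto). An F1 between divergent parents is heterozygous at their
   fixed differences.
3. **Diagnostic SNPs** — alleles carried by every individual of one
   photosynthetic group and by none of the others (≤ 25% missing data per
   group). A hybrid should carry exactly **one allele diagnostic of each
   parental group**; the hypothesis (C3 × C4 vs C3+C4 × C4) reaching 90%
   site consistency wins.
4. **Paternity by singleton matching** — a *singleton* is a homozygous
   genotype unique to one candidate within its photosynthetic type. For
   each candidate, count the hybrid's positive matches (carrying ≥ 1 copy
   of the singleton allele) over its tested singletons; assign the top
   candidate when its match fraction leads the runner-up by ≥ 0.2,
   otherwise report `ambiguous`.

On the phenotype side, A/Ci curves are fitted with the empirical
nonrectangular hyperbola — gross assimilation *G* is the lower root of
θG² − G(CE·Ci + A_sat) + CE·Ci·A_sat = 0 and net assimilation A = G − R —
yielding the maximum carboxylation efficiency CE (initial slope), the CO2
compensation point (the zero of fitted A, by bracketed root finding), and
steady-state A400, gs400 and iWUE = A400/gs400. δ13C values above −16 ‰
classify a plant as having grown using C4 photosynthesis. Expression
utilities implement reads-per-million normalisation, the > 10 RPM in ≥ 5
samples filter, log2 transformation and the base-mean > 500 /
|log2FC| > 1 / adjusted p < 0.05 post-filter; `midparent_analysis()`
quantifies hybrid additivity as deviation from the mid-parent value and a
scaled dominance index.

Everything is validated against a seed-deterministic simulator
(`simulate_panel()`, `simulate_cross()`, `apply_observation_model()`,
`simulate_aci_cohort()`, `simulate_trait_table()`) that emits full ground
truth; see the methods vignette (`vignettes/hybridtyper-methods.Rmd`) for
the models and design decisions.

## Worked example

Simulate a small study — a 3-lineage panel, five F1s with known mothers,
an RNA-seq-like observation layer — then run the typing chain:

```r
library(hybridtyper)
library(dplyr)

sim <- simulate_study(panel_config(n_sites = 5000, seed = 42),
                      n_crosses = c("C3" = 3, "C3+C4" = 2),
                      obs = obs_config(), seed = 42)

gm  <- sim$gm |> filter_calls() |> filter_sites(0.10)
inf <- select_informative_sites(gm)
inf
#> <geno_matrix> 90 sites x 17 samples
#>   samples: candidate_parent=12, hybrid_candidate=5
#>   filter log:
#>     observation_model(depth=20, error=0.01, missing=0.1)
#>     filter_calls(min_quality=30, min_depth=3): masked 5466 of 76387 calls
#>     indels: 5000 -> 5000
#>     missingness(max=0.1): 5000 -> 1022
#>     informative: 1022 -> 90

diag <- find_group_diagnostic_snps(inf)
classify_cross_types(inf, diag)
#>   hybrid_id mother_id mother_group hypothesis sites_tested sites_consistent
#> 1 H01_1     C3_4      C3           C3xC4                 7                7
#> 2 H02_1     C3_4      C3           C3xC4                 7                7
#> 3 H03_1     C3_4      C3           C3xC4                 7                7
#> 4 H04_1     C3C4_2    C3+C4        C3+C4xC4              6                6
#> 5 H05_1     C3C4_4    C3+C4        C3+C4xC4              6                6

fathers <- gm$samples$sample_id[gm$samples$group == "C4" &
                                gm$samples$role == "candidate_parent"]
sing <- find_parent_singletons(inf, fathers)
assign_pollen_parents(inf, sing) |>
  select(hybrid_id, assigned_parent, verdict, margin)
#>   hybrid_id assigned_parent verdict  margin
#> 1 H01_1     C4_1            assigned      1
#> 2 H02_1     C4_2            assigned      1
#> 3 H03_1     C4_1            assigned      1
#> 4 H04_1     C4_4            assigned      1
#> 5 H05_1     C4_1            assigned      1
```

Each hybrid's cross type matches its true pedigree (`sim$truth$pedigree`),
and every assigned pollen parent is the true father: the hybrids match
(essentially) all of the father's singletons and none of the other
candidates', hence margins of 1.

Fitting a noisy C3-like A/Ci curve:

```r
cur <- simulate_aci_cohort(n_per_group = 1, noise_sd = 0.3, seed = 9)
f <- fit_aci(filter(cur$curves, group == "C3"), seed = 9)
f
#> <hyperbola_fit> C3_aci_1 (14 obs, converged)
#>   CE=0.07378  A_sat=23.11  theta=0.802  R=3.134  CCP=43.8  RSS=1.85
glance(f)   # one-row tibble; tidy(f) gives one row per parameter
autoplot(f) # observations, fitted hyperbola, CCP
```

The fitted compensation point (43.8 µmol mol⁻¹) is in the C3 band, and
`steady_state_metrics()` / `flag_tleaf_outliers()` complete the
physiology workflow.

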