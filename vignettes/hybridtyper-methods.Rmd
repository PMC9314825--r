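---
title: "Methods: hybrid typing, parentage assignment and photosynthetic phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid typing, parentage assignment and photosynthetic phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridtyper)
library(dplyr)
```

# The scientific problem

The grass *Alloteropsis semialata* contains C3, C4 and intermediate
(C3+C4) photosynthetic lineages that still hybridise. Given RNA-seq-derived
genotype calls for a set of putative F1 hybrids, their known mothers (the
plants the seeds were collected from) and a panel of candidate pollen
parents, `hybridtyper` answers three questions:

1. **Is a plant really an F1 between photosynthetic types?** An F1 between
   deeply divergent parents is heterozygous wherever its parents carry
   fixed differences.
2. **What type of cross is it** (C3 × C4 or C3+C4 × C4)? Decided from
   lineage-diagnostic SNPs: the hybrid should carry exactly one allele
   diagnostic of each parental group.
3. **Which individual was the pollen parent?** Decided by counting matches
   to each candidate's *singletons* — homozygous genotypes unique to that
   individual within its photosynthetic type. An F1 receives one paternal
   allele, so it should carry the true father's singleton alleles and
   almost none of the others'.

The package also implements the phenotype-side computations used alongside
this genotyping: nonrectangular-hyperbola fitting of A/Ci gas-exchange
curves, δ13C classification of photosynthetic operation, expression
normalisation/filtering rules, and mid-parent additivity indices. A
seed-deterministic simulator generates all of these data types with ground
truth, so every inference step is validated by recovery tests.

# Genotype filtering

Filtering happens in two stages with deliberately strict (exclusive)
boundaries:

* `filter_calls()` masks individual genotype calls with genotype quality
  below 30 or read depth below 3 reads. A call at exactly GQ 30 and DP 3 is
  kept. Masking never removes sites; it converts calls to the missing
  state, which the site filter then sees. If a VCF carries no per-sample GQ
  at all, the site-level QUAL is used for every call of the site (with one
  warning); if it carries no per-sample DP, the depth criterion is skipped.
  A call whose individual annotation is absent while others are present is
  retained — it cannot be judged.
* `filter_sites()` removes indels and sites with *more than* 10% missing
  calls (1 missing call in 10 samples is kept; 2 are not).

Both filters are idempotent and monotone in their thresholds, and both log
`"name: before -> after"` lines retrievable with `geno_log()`.

# The typing chain

**Informative sites** (`select_informative_sites()`) are polymorphic sites
where every hybrid candidate with a non-missing call is heterozygous and
every candidate parent with a non-missing call is homozygous, with at
least one non-missing call per role. Missing calls do not veto a site: the
matrix has already been capped at 10% missingness, and demanding complete
data would discard most of the genome for no inferential gain.

**Diagnostic SNPs** (`find_group_diagnostic_snps()`) carry an allele
present in every non-missing individual of one photosynthetic group and in
no individual of any other; sites with more than 25% missing data within
any group are excluded first. Presence means carrying at least one copy —
fixation of the *allele* in the group is not required to be homozygous.

A design point worth spelling out: when hybrids of both cross types are in
the cohort, the only sites that both (a) survive the
all-hybrids-heterozygous filter and (b) distinguish C3 from C3+C4 mothers
are **multi-allelic**, e.g. a site where the C3 group is fixed for T, the
C3+C4 group for A and the C4 group for G. At such a tri-group fixed
difference every hybrid is heterozygous whatever its cross, yet the
maternal allele identifies the maternal group. The cross-type test is
therefore defined on per-allele diagnosis labels rather than restricted to
biallelic configurations.

**Cross-type classification** (`classify_cross_type()`) evaluates one
hypothesis per non-C4 group (C3 × C4 and C3+C4 × C4). A diagnostic site
*tests* a hypothesis only when it carries diagnostic alleles for both
sides of that cross; it is *consistent* when the hybrid carries exactly
one copy of each such allele and no copy of alleles diagnostic of groups
outside the cross. The two-sided requirement matters in practice: an
individual-private site whose owner's call happens to be missing can
masquerade as a single-group diagnostic site, and such one-sided sites
carry no information about the cross. The hypothesis reaching a
consistency of `min_consistency` (default 0.9, tolerating low-level
genotyping error while rejecting non-F1s) wins; both passing yields
`"ambiguous"`, neither `"not_F1"`, and a hybrid without a testable site is
explicitly `"untestable"` rather than silently passed.

**Singletons and paternity** (`find_parent_singletons()`,
`assign_pollen_parent()`). A singleton is a homozygous genotype unique to
one individual among the non-hybrid individuals of its photosynthetic
group. A hybrid *matches* a singleton when it carries at least one copy of
the singleton allele — heterozygosity is not demanded, because the hybrid
receives only one paternal allele (and the definition must also hold if
the maternal lineage happens to share it). Candidates are ranked by match
fraction over their tested singletons; the top candidate is assigned only
when its fraction leads the runner-up by at least `min_margin` (default
0.2). Equal fractions — e.g. two accessions of one unresolvable lineage —
give an honest `"ambiguous"`, a single testable candidate `"degenerate"`,
and no testable site `"untestable"`. No randomness is used anywhere in the
chain; permuting sample order changes nothing.

# A/Ci curve fitting

Net CO2 assimilation is modelled as an empirical nonrectangular hyperbola:
gross assimilation $G$ is the lower root of

$$\theta G^2 - G\,(CE \cdot C_i + A_{sat}) + CE \cdot C_i \cdot A_{sat} = 0,$$

and net assimilation is $A = G - R$. The parameters, with units and
bounds:

| parameter | meaning | unit | bounds | initial value |
|---|---|---|---|---|
| $CE$ | maximum carboxylation efficiency (initial slope) | µmol m⁻² s⁻¹ / (µmol mol⁻¹) | (0, 5] | OLS slope of the ≤3 lowest-$C_i$ points |
| $A_{sat}$ | asymptotic gross assimilation | µmol m⁻² s⁻¹ | (0, 200] | max $A$ + offset |
| $\theta$ | curvature | — | (0.01, 1] | 0.7 |
| $R$ | apparent respiratory offset | µmol m⁻² s⁻¹ | [0, 20] | $-\min(A, 0) + 1$ |

The empirical form makes no mechanistic assumption about the pathway, so
the same fit applies to C3, C4, intermediate and hybrid physiology —
which is the point, since hybrids are neither. Fitting is bounded
Levenberg–Marquardt (`minpack.lm::nlsLM`) from `n_starts = 10`
lognormally jittered initialisations (seeded; identical seed and data give
identical fits), keeping the best residual sum of squares. The CO2
compensation point is the non-negative zero of the fitted $A(C_i)$, found
by bracketed root finding (`uniroot`, tolerance 1e-10, bracket expanded
until $A > 0$); $A(\mathrm{CCP}) = 0$ holds to below 1e-6 for every
converged fit. $CE$ is reported as the fitted initial-slope parameter
(the slope at $C_i = 0$), not the slope at the compensation point; with
$\theta \to 1$ the model degenerates to $\min(CE \cdot C_i, A_{sat}) - R$
and $CE$ is exactly the low-$C_i$ slope. The return-to-ambient
measurement (the second 400 step of the sequence) is included in fitting
by default and can be excluded with a flag.

Steady-state metrics are taken from the *first* observation at reference
CO2 = 400 µmol mol⁻¹ (the pre-ramp acclimated reading, not the return
point): $A_{400}$, $g_{s400}$ and intrinsic water-use efficiency
$iWUE = A_{400}/g_{s400}$. Leaf-temperature quality control flags curves
whose median $T_{leaf}$ exceeds the grand median of all observations by
more than 1 °C (strict).

# What the simulator emulates — and what it does not

`simulate_panel()` plants four site classes in configurable proportions
(defaults: 55.2% shared polymorphism, 0.8% diagnostic, 24%
individual-private, 20% monomorphic over 15,000 sites — the scale of an
RNA-seq-derived informative-site panel, giving ~120 diagnostic sites and
~300 private sites per panel individual, mirroring a realistic study):

* **Diagnostic sites** are tri-group fixed differences (group $j$
  homozygous for allele $j$), the only configuration that stays
  F1-informative for both cross types while identifying the maternal
  lineage (see above).
* **Private sites** give the owner a homozygous private allele (allele 2)
  while its own group is fixed for allele 1 and other groups for allele 0.
  This three-allele layout keeps the site informative in multi-father
  cohorts: every hybrid is heterozygous, all parents homozygous, and
  exactly one candidate is marked.
* **Shared sites** segregate at a common U(0.1, 0.9) frequency in all
  groups and are rejection-resampled so that no shared site accidentally
  satisfies the diagnostic or singleton definition. This makes the planted
  sets *exactly* the discoverable sets at zero noise, so recovery tests
  can assert set equality rather than overlap.

`simulate_cross()` draws one allele from each parent per site,
independently across sites. `apply_observation_model()` layers
negative-binomial read depth (mean 20, size 5), a depth-to-quality map
(default $\min(99, 4 \cdot \mathrm{depth})$), genotype errors (a random
*different* genotype of the site's alleles) and missingness on top.

`simulate_aci_cohort()` draws hyperbola parameters per individual and
calibrates group physiology through the compensation point: CCP is drawn
uniformly from the group band (C3 43.5–47.5, C3+C4 5–15, C4 2–9
µmol mol⁻¹) and $R$ is derived from it, so the planted physiology spans
the ranges reported for the species. Intercellular CO2 is solved
self-consistently from the stomatal drawdown
$C_i = C_a - 1.6\,A/g_s$ — near the compensation point $A \approx 0$ and
$C_i \approx C_a$, which is exactly why the measurement sequence's low
steps (50, 35 µmol mol⁻¹) bracket a C3 compensation point; a fixed
$C_i/C_a$ ratio would misplace them. Stomatal conductance is calibrated
so that C4 $iWUE$ sits ~38% above the non-C4 groups, the contrast
reported for the species. Gaussian noise (default σ = 0.5 µmol m⁻² s⁻¹)
applies to $A$ only.

`simulate_trait_table()` sets each hybrid to
$\mathrm{midparent} + d \cdot (\mathrm{high\ parent} - \mathrm{midparent})$
plus noise scaled by the parental difference, so the scaled-dominance
index recovered by `midparent_analysis()` equals the planted $d$ exactly
at zero noise.

**Known limitations.** Sites are unlinked (the inference chain never uses
linkage, but real RNA-seq SNPs are clustered within genes); allelic
expression bias — a genuine hazard of RNA-seq genotyping, where one
parental allele of a gene may dominate the reads — is folded into the
generic genotype error rate rather than modelled as directional dropout;
depth is independent across sites, whereas real coverage follows gene
expression. Passing recovery tests therefore show the *inference rules*
are implemented correctly and are robust to exchangeable noise, not that
real RNA-seq data will behave this well; in real data the informative-site
and diagnostic filters inherit whatever systematic biases the upstream
mapping and calling left behind.

# Numerical choices and test scale

All threshold comparisons are strict as documented. Paternity ties are
resolved by the margin rule, with alphabetical candidate order used only
to make ranking deterministic at exactly equal fractions (the verdict
there is `"ambiguous"` regardless). Root finding uses tolerance 1e-10;
fits declare `converged = FALSE` only when every start fails. Degenerate
inputs (fewer than 4 distinct $C_i$, constant $A$, empty singleton sets,
hybrids with no testable site) raise errors or explicit verdicts, never
silent passes.

The validation suite runs the pedigree-recovery study at 15,000 sites ×
32 samples × 10 replicates (1% genotype error, 10% missingness) and the
A/Ci recovery study on 200 noisy curves; both are the package's chosen
study-scale conditions and complete in a few minutes.

One honest negative result from the recovery study: at σ = 0.5 the
*median relative* CCP error pooled over the three-group cohort is ~12–14%,
above a 10% figure one might hope for. This is information-limited, not an
optimiser defect: refitting fresh noise replicates of a single known
C4-like curve from its true parameters gives an unbiased CCP estimate
(mean 5.4 for truth 5.5) with sampling sd ~1.7 µmol mol⁻¹ — ~20% relative
spread for a compensation point below 10 µmol mol⁻¹, because no
measurable point sits near the zero crossing. C3-scale compensation points
(~45 µmol mol⁻¹) are recovered with ~5% median error. Absolute CCP errors
are small and group contrasts are recovered cleanly; only the relative
error on near-zero compensation points is noise-floor-limited.

# Session info

```{r}
sessionInfo()
```
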