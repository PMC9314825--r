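Package: hybridtyper
Title: F1 Hybrid Typing and Pollen-Parent Assignment from RNA-Seq SNPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects F1 hybrids between divergent photosynthetic lineages
    (C3, C3+C4 and C4) from multi-sample genotype calls and assigns the
    pollen parent by singleton-allele matching. Implements the supporting
    genotype filters (per-call quality and depth masking, indel and
    missingness site filters), discovery of lineage-diagnostic SNPs,
    cross-type classification of hybrids, and count-based paternity
    assignment. Also provides the phenotype-side computations used in
    hybrid physiology studies: nonrectangular-hyperbola fitting of A/Ci
    gas-exchange curves with CO2 compensation point and carboxylation
    efficiency estimation, intrinsic water-use efficiency, leaf-temperature
    quality control, reads-per-million normalisation and expression
    filters, carbon-isotope (delta 13C) classification of photosynthetic
    operation, and mid-parent additivity indices. A seed-deterministic
    synthetic-data generator simulates lineage panels, diploid crosses,
    observation noise, gas-exchange cohorts and trait tables with full
    ground truth, so every stage of the pipeline is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
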