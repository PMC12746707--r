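Package: coseg
Title: Two-Locus Haplotype Co-Segregation, IBD Detection and Companion
    Statistics for Compound-Inheritance Family Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating compound (two-locus) inheritance in nuclear
    families. Provides the exact probability of a specified two-locus haplotype
    segregation pattern under the Haldane mapping function together with a
    Monte-Carlo meiosis oracle; identity-by-descent (IBD) segment detection
    from family-scale multi-sample VCFs with per-sample depth, quality,
    Mendelian-consistency and allelic-balance filters; allele-frequency tiers
    and ACMG/AMP evidence combination for variant classification; a degree-
    and weight-preserving network-randomization null for gene-gene functional
    proximity with empirical p-values and Benjamini-Hochberg correction;
    phenotype tally statistics for larval injection experiments; and
    synthetic-data generators (meioses with Poisson crossovers, noisy VCFs,
    planted-module weighted networks, phenotype and angle tables) so every
    stage is testable without external data.
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
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
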