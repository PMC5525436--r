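Package: lipidgwis
Title: Two-Arm SNP-SNP Interaction Discovery and Multi-Cohort Replication
    for Quantitative Lipid Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering and replicating pairwise SNP-SNP
    (epistatic) interactions on quantitative lipid traits (HDL-C, LDL-C,
    total cholesterol, triglycerides) with a linear-regression likelihood
    ratio test. Implements the two classic candidate-model arms -- main
    effect filtering with exhaustive pairing, and knowledge-driven
    gene-pair models -- together with the surrounding machinery: lipid
    phenotype preparation (unit conversion, Friedewald LDL derivation,
    log-triglyceride transform), genotype quality control (call rates,
    Hardy-Weinberg exact test, minor allele frequency, identity-by-descent
    relatedness, principal components), linkage-disequilibrium utilities
    (pairwise r2, pruning, proxy discovery, signal-set grouping), and
    multi-cohort replication with Bonferroni-like thresholds and LD-signal
    collapsing. A multi-cohort synthetic-data generator with LD-block
    structured genotypes and planted interactions makes every stage
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
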