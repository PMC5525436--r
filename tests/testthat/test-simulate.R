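# Synthetic multi-cohort generator: determinism, LD structure,
# covariate contracts, phenotype construction and cohort splitting.

test_that("identical config and seed reproduce identical outputs", {
  cfg <- sim_config(n_cohorts = 2, n_per_cohort = 50, n_snps = 8,
                    ld_block_sizes = c(4, 4), within_block_r2 = 0.5,
                    seed = 99)
  expect_identical(simulate_genotypes(cfg)$dosage,
                   simulate_genotypes(cfg)$dosage)
  expect_identical(simulate_covariates(40, seed = 3),
                   simulate_covariates(40, seed = 3))
  st1 <- simulate_study(cfg)
  st2 <- simulate_study(cfg)
  expect_identical(st1$phenotypes, st2$phenotypes)
  genes <- simulate_gene_annotation(st1$genotypes)
  expect_identical(simulate_knowledge_base(genes, 5, 0.5, seed = 7),
                   simulate_knowledge_base(genes, 5, 0.5, seed = 7))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_snps = 10, ld_block_sizes = c(4, 4)),
               "ld_block_sizes")
  expect_error(sim_config(within_block_r2 = 1), "within_block_r2")
  expect_error(sim_config(maf_range = c(0.01, 0.5)), "maf_range")
  expect_error(true_effect("a", beta_interaction = 0.5), "snp_b")
})

test_that("dosages are valid and blocks carry the target LD", {
  cfg <- sim_config(n_cohorts = 1, n_per_cohort = 5000, n_snps = 10,
                    ld_block_sizes = 10, within_block_r2 = 0.9,
                    seed = 7)
  G <- simulate_genotypes(cfg)
  expect_true(all(G$dosage %in% c(0, 1, 2) | is.na(G$dosage)))
  d <- G$dosage
  adj <- vapply(1:9, function(j) {
    suppressWarnings(pairwise_r2(d[, j], d[, j + 1]))
  }, numeric(1))
  expect_gt(mean(adj), 0.8)
  expect_lt(mean(adj), 0.95)
})

test_that("zero target LD gives near-independent SNPs within blocks", {
  cfg <- sim_config(n_cohorts = 1, n_per_cohort = 2000, n_snps = 6,
                    ld_block_sizes = 6, within_block_r2 = 0,
                    missing_rate = 0, seed = 5)
  G <- simulate_genotypes(cfg)
  r2 <- ld_matrix(G)$r2
  expect_lt(mean(r2[upper.tri(r2)]), 0.01)
})

test_that("within-block r2 is monotone in the target", {
  targets <- c(0, 0.3, 0.6, 0.9)
  means <- vapply(targets, function(t) {
    cfg <- sim_config(n_cohorts = 1, n_per_cohort = 5000, n_snps = 6,
                      ld_block_sizes = 6, within_block_r2 = t,
                      missing_rate = 0, seed = 31)
    d <- simulate_genotypes(cfg)$dosage
    mean(vapply(1:5, function(j) {
      suppressWarnings(pairwise_r2(d[, j], d[, j + 1]))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("covariate table honors its contracts", {
  X <- simulate_covariates(100, seed = 2)
  expect_equal(nrow(X), 100)
  expect_equal(ncol(X) - 1L, 16L)  # 6 clinical + 10 PCs
  expect_true(all(X$age >= 21))
  expect_true(all(X$age <= 80))
  expect_true(all(X$sex %in% 0:1))
  expect_error(simulate_covariates(0), "positive")
})

test_that("pure-noise phenotypes have unit variance at scale", {
  cfg <- sim_config(n_cohorts = 1, n_per_cohort = 5000, n_snps = 2,
                    ld_block_sizes = c(1, 1), within_block_r2 = 0,
                    covariate_effects = c(age = 0), noise_sd = 1,
                    missing_rate = 0, seed = 13)
  st <- simulate_study(cfg)
  expect_equal(var(st$phenotypes$hdl), 1, tolerance = 0.06)
  expect_equal(var(st$phenotypes$ldl), 1, tolerance = 0.06)
  expect_equal(var(log(st$phenotypes$tg)), 1, tolerance = 0.06)
})

test_that("TC obeys the Friedewald identity when its noise is zero", {
  cfg <- sim_config(n_cohorts = 1, n_per_cohort = 500, n_snps = 2,
                    ld_block_sizes = c(1, 1), within_block_r2 = 0,
                    noise_sd = c(HDL = 0.3, LDL = 0.8, TG = 0.4, TC = 0),
                    missing_rate = 0, seed = 17)
  st <- simulate_study(cfg)
  P <- st$phenotypes
  expect_equal(P$tc, P$ldl + P$hdl + 0.45 * P$tg, tolerance = 1e-12)
})

test_that("true effects referencing absent SNPs are rejected", {
  cfg <- sim_config(n_cohorts = 1, n_per_cohort = 50, n_snps = 2,
                    ld_block_sizes = c(1, 1), within_block_r2 = 0,
                    true_effects = list(true_effect("nope", trait = "HDL",
                                                    beta_main_a = 1)),
                    seed = 1)
  G <- simulate_genotypes(cfg)
  X <- simulate_covariates(50, seed = 2, sample_ids = sample_ids(G))
  expect_error(simulate_phenotypes(G, X, cfg), "absent")
})

test_that("cohort splitting is a disjoint partition with role flags", {
  cfg <- sim_config(n_cohorts = 3, n_per_cohort = 100, n_snps = 4,
                    ld_block_sizes = c(2, 2), within_block_r2 = 0,
                    n_discovery_cohorts = 2, seed = 8)
  st <- simulate_study(cfg)
  ids <- lapply(st$cohorts, function(co) sample_ids(co$genotypes))
  expect_setequal(unlist(ids), sample_ids(st$genotypes))
  expect_length(intersect(ids[[1]], ids[[2]]), 0)
  expect_length(intersect(ids[[2]], ids[[3]]), 0)
  expect_equal(vapply(st$cohorts, `[[`, "", "role"),
               c("discovery", "discovery", "replication"))

  bad <- cfg
  bad$n_per_cohort <- c(100L, 100L, 200L)
  expect_error(split_cohorts(st$genotypes, st$covariates,
                             st$phenotypes, bad), "exceeds")
})

test_that("knowledge base density endpoints behave", {
  genes <- data.frame(gene = c("G1", "G2", "G3"), chrom = "1",
                      start = c(0, 100, 200), end = c(50, 150, 250))
  expect_equal(nrow(simulate_knowledge_base(genes, 6, 0, seed = 1)), 0)
  full <- simulate_knowledge_base(genes, 6, 1, seed = 1)
  counts <- table(paste(full$gene1, full$gene2))
  expect_equal(length(counts), 3L)         # all C(3,2) pairs
  expect_true(all(counts == 6))
  expect_error(simulate_knowledge_base(genes, 0, 0.5), "n_sources")
  expect_error(simulate_knowledge_base(genes[1, ], 3, 0.5), "2 genes")
})
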