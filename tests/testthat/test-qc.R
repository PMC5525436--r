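# Genotype/sample QC: call rates, Hardy-Weinberg exact test, MAF,
# relatedness by pi-hat, principal components, report replay.

make_callrate_fixture <- function() {
  # 100 samples x 3 SNPs: snp1 96/100 calls, snp2 94/100, snp3 complete
  d <- matrix(rep(c(0, 1, 2, 1), 75), 100, 3)
  d[1:4, 1] <- NA
  d[1:6, 2] <- NA
  toy_genotypes(d)
}

test_that("SNP call-rate boundary is inclusive at the threshold", {
  g <- make_callrate_fixture()
  res <- snp_call_rate_filter(g, 0.95)
  expect_equal(res$removed, "t02")            # 94/100 < 0.95
  expect_true("t01" %in% snp_ids(res$genotypes))  # 96/100 kept
  complete <- toy_genotypes(matrix(rep(c(0, 1, 2), 10), 10, 3))
  expect_length(snp_call_rate_filter(complete, 0.95)$removed, 0)
})

test_that("sample call-rate filter removes low-call samples", {
  d <- matrix(rep(c(0, 1), 100), 10, 100)
  d[1, 1:11] <- NA   # 89% calls
  d[2, 1:9] <- NA    # 91% calls
  g <- toy_genotypes(d)
  res <- sample_call_rate_filter(g, 0.90)
  expect_equal(res$removed, "I001")
  expect_true("I002" %in% sample_ids(res$genotypes))
})

test_that("filters are idempotent", {
  g <- make_callrate_fixture()
  once <- snp_call_rate_filter(g, 0.95)$genotypes
  twice <- snp_call_rate_filter(once, 0.95)$genotypes
  expect_identical(once$dosage, twice$dosage)
  m1 <- maf_filter(g, 0.05)$genotypes
  m2 <- maf_filter(m1, 0.05)$genotypes
  expect_identical(m1$dosage, m2$dosage)
})

test_that("MAF filter folds frequencies and keeps the boundary", {
  # f = 0.05 exactly: dosage sum 10 over 100 samples
  d1 <- c(rep(1, 10), rep(0, 90))
  # f = 0.96 -> MAF 0.04: removed
  d2 <- c(rep(2, 92), rep(1, 8))  # mean dosage 1.92
  g <- toy_genotypes(cbind(d1, d2))
  res <- maf_filter(g, 0.05)
  expect_equal(snp_ids(res$genotypes), "t01")
  expect_equal(res$removed, "t02")
  expect_length(maf_filter(g, 0)$removed, 0)
  nocall <- toy_genotypes(cbind(d1, rep(NA_real_, 100)))
  expect_warning(res2 <- maf_filter(nocall, 0.05), "zero non-missing")
  expect_equal(res2$removed, "t02")
})

test_that("exact HWE test matches hand-enumerated small cases", {
  expect_equal(hwe_exact_test(100, 0, 0), 1.0)    # monomorphic
  # 2 minor alleles in 2 individuals: het counts {0, 2} have
  # probabilities {1/3, 2/3}; observing the mode gives p = 1
  expect_equal(hwe_exact_test(0, 2, 0), 1.0)
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)
  expect_error(hwe_exact_test(0, 0, 0), "zero")
  expect_error(hwe_exact_test(-1, 2, 0), "nonnegative")
})

test_that("exact HWE test equals the enumeration oracle (random draws)", {
  set.seed(404)
  for (i in 1:300) {
    n <- sample(1:50, 1)
    n_AA <- sample(0:n, 1)
    n_Aa <- sample(0:(n - n_AA), 1)
    n_aa <- n - n_AA - n_Aa
    expect_equal(hwe_exact_test(n_AA, n_Aa, n_aa),
                 hwe_oracle(n_AA, n_Aa, n_aa), tolerance = 1e-12)
  }
})

test_that("exact HWE test is stable at large sample sizes", {
  p <- hwe_exact_test(3000, 5000, 3000)
  expect_gt(p, 0)
  expect_lte(p, 1)
  # strong heterozygote deficit must be detected
  expect_lt(hwe_exact_test(5000, 1000, 5000), 1e-100)
})

test_that("pi-hat flags duplicates and is near zero for unrelateds", {
  g <- random_genotypes(20, runif(600, 0.2, 0.5), seed = 11)
  dup <- genotype_matrix(rbind(g$dosage, dup1 = g$dosage[1, ]),
                         g$snps,
                         c(sample_ids(g), "Idup"))
  ph <- estimate_ibd_pihat(dup)
  pair <- ph[ph$id1 == "I001" & ph$id2 == "Idup", ]
  expect_gte(pair$pihat, 0.95)
  unrel <- ph[ph$id1 != "I001" & ph$id2 != "Idup", ]
  expect_lt(abs(mean(unrel$pihat_raw)), 0.05)
  expect_true(all(unrel$pihat_raw > -0.25 & unrel$pihat_raw < 0.25))
  expect_true(all(ph$pihat >= 0 & ph$pihat <= 1))
})

test_that("pi-hat warns when too few informative SNPs remain", {
  g <- random_genotypes(5, rep(0.4, 20), seed = 3)
  expect_warning(estimate_ibd_pihat(g), "fewer than 50")
})

test_that("relatedness removal drops one per pair, two per triangle", {
  g <- random_genotypes(6, rep(0.4, 100), seed = 9)
  mk <- function(i, j, v) data.frame(id1 = sprintf("I%03d", i),
                                     id2 = sprintf("I%03d", j),
                                     pihat = v, pihat_raw = v,
                                     n_snps = 100)
  all_pairs <- do.call(rbind, lapply(combn(6, 2, simplify = FALSE),
    function(p) mk(p[1], p[2], 0.01)))

  one_pair <- all_pairs
  one_pair$pihat[one_pair$id1 == "I001" & one_pair$id2 == "I002"] <- 0.9
  res <- remove_related(g, one_pair, 0.3)
  expect_length(res$removed, 1)
  expect_true(res$removed %in% c("I001", "I002"))

  expect_length(remove_related(g, all_pairs, 0.3)$removed, 0)

  tri <- all_pairs
  for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
    tri$pihat[tri$id1 == sprintf("I%03d", p[1]) &
                tri$id2 == sprintf("I%03d", p[2])] <- 0.8
  }
  res3 <- remove_related(g, tri, 0.3)
  # minimal vertex cover of a triangle has size 2
  expect_length(res3$removed, 2)
  expect_true(all(res3$removed %in% c("I001", "I002", "I003")))
})

test_that("principal components are orthogonal, ordered and separating", {
  set.seed(21)
  # two subpopulations with divergent allele frequencies
  p1 <- runif(80, 0.1, 0.3); p2 <- pmin(0.9, p1 + 0.35)
  d <- rbind(
    vapply(p1, function(p) rbinom(60, 2, p), numeric(60)),
    vapply(p2, function(p) rbinom(60, 2, p), numeric(60)))
  g <- toy_genotypes(d)
  pcs <- compute_pcs(g, k = 5)
  gram <- crossprod(pcs)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-6)
  ve <- attr(pcs, "var_explained")
  expect_true(all(diff(ve) <= 1e-12))
  grp <- rep(1:2, each = 60)
  mu <- tapply(pcs[, 1], grp, mean)
  pooled_sd <- sqrt(mean(tapply(pcs[, 1], grp, var)))
  expect_gt(abs(diff(mu)) / pooled_sd, 2)
  expect_error(compute_pcs(g, k = 200), "smaller")
})

test_that("QC report replay reproduces the output bit-exactly", {
  cfg <- sim_config(n_cohorts = 1, n_per_cohort = 120, n_snps = 12,
                    ld_block_sizes = rep(3, 4), within_block_r2 = 0.4,
                    missing_rate = 0.05, seed = 55)
  g <- simulate_genotypes(cfg)
  qc <- suppressWarnings(
    run_genotype_qc(g, snp_call_rate = 0.93, sample_call_rate = 0.85))
  expect_identical(apply_qc_report(g, qc$report)$dosage,
                   qc$genotypes$dosage)
  expect_equal(qc$report$steps,
               c("snp_callrate", "hwe", "sample_callrate",
                 "relatedness", "maf"))
  expect_true(all(qc$report$counts >= 0))
})
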