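# The interaction LRT: OLS core, reduced-vs-full comparison, batch
# behavior.

test_that("OLS matches the closed-form normal equations on a toy fit", {
  X <- cbind(1, c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 6))
  y <- c(1.2, 1.9, 3.4, 3.8, 5.6)
  fit <- fit_linear(y, X)
  beta_hat <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$coef, as.numeric(beta_hat), tolerance = 1e-10)
  lmfit <- lm(y ~ X[, 2] + X[, 3])
  expect_equal(fit$coef, unname(coef(lmfit)), tolerance = 1e-10)
  expect_equal(fit$se, unname(sqrt(diag(vcov(lmfit)))), tolerance = 1e-8)
  expect_equal(fit$r2, summary(lmfit)$r.squared, tolerance = 1e-10)
  expect_equal(fit$loglik, as.numeric(logLik(lmfit)), tolerance = 1e-8)
})

test_that("OLS handles degenerate designs without crashing", {
  X <- cbind(1, 1:6, 2 * (1:6))           # collinear
  expect_equal(fit_linear(rnorm(6), X)$status, "collinear")
  # intercept-only model: R2 = 0
  expect_equal(fit_linear(rnorm(20), matrix(1, 20, 1))$r2, 0)
  # exact fit: guarded log-likelihood
  X2 <- cbind(1, 1:10)
  fit <- fit_linear(2 + 3 * (1:10), X2)
  expect_equal(fit$status, "ok")
  expect_true(fit$exact_fit)
  expect_equal(fit$loglik, Inf)
})

test_that("pure additive zero-noise data give a null LRT", {
  set.seed(10)
  g <- random_genotypes(200, c(0.3, 0.4), seed = 10)
  X <- simulate_covariates(200, seed = 11, sample_ids = sample_ids(g))
  y <- 1 + 0.5 * g$dosage[, 1] - 0.3 * g$dosage[, 2] + 0.01 * X$age
  res <- lrt_interaction(data.frame(snp_a = "t01", snp_b = "t02"),
                         g, y, X)
  expect_equal(res$lrt_stat, 0, tolerance = 1e-8)
  expect_equal(res$p_lrt, 1, tolerance = 1e-6)
})

test_that("a planted interaction coefficient is recovered within 3 SE", {
  st <- simulate_study(planted_config(n = 5000, beta_int = 0.5,
                                      seed = 37))
  res <- batch_test(data.frame(snp_a = "snp0001", snp_b = "snp0002",
                               provenance = "mef"),
                    st$cohorts[[1]], "hdl")
  expect_equal(res$status, "ok")
  expect_lt(abs(res$beta_int - 0.5), 3 * res$se_int)
  expect_lt(res$p_lrt, 1e-10)
})

test_that("LRT agrees with 2*delta-loglik and with the partial F test", {
  st <- simulate_study(planted_config(n = 3000, beta_int = 0.03,
                                      seed = 41))
  co <- st$cohorts[[1]]
  res <- lrt_interaction(data.frame(snp_a = "snp0001", snp_b = "snp0002"),
                         co$genotypes, co$phenotypes$hdl, co$covariates)

  covs <- intersect(default_covariates(), names(co$covariates))
  df <- cbind(y = co$phenotypes$hdl,
              ga = co$genotypes$dosage[, 1],
              gb = co$genotypes$dosage[, 2],
              co$covariates[, covs])
  df <- df[complete.cases(df), ]
  f_r <- lm(y ~ ., data = df)
  f_f <- update(f_r, . ~ . + ga:gb)
  # RSS-ratio statistic equals 2 * delta log-likelihood
  expect_equal(res$lrt_stat,
               2 * (as.numeric(logLik(f_f)) - as.numeric(logLik(f_r))),
               tolerance = 1e-8)
  # chi-square(1) p close to the partial F-test p at this n
  p_f <- anova(f_r, f_f)$`Pr(>F)`[2]
  expect_gt(res$p_lrt, 0.001)  # a moderate p where % comparison is fair
  expect_lt(abs(res$p_lrt - p_f) / p_f, 0.02)
  expect_gte(res$diff_r2, -1e-12)
})

test_that("results are invariant to row order and SNP swap", {
  st <- simulate_study(planted_config(n = 800, beta_int = 0.3, seed = 51))
  co <- st$cohorts[[1]]
  m <- data.frame(snp_a = "snp0001", snp_b = "snp0002")
  m_swap <- data.frame(snp_a = "snp0002", snp_b = "snp0001")
  r1 <- lrt_interaction(m, co$genotypes, co$phenotypes$hdl,
                        co$covariates)
  r2 <- lrt_interaction(m_swap, co$genotypes, co$phenotypes$hdl,
                        co$covariates)
  expect_equal(r1$lrt_stat, r2$lrt_stat, tolerance = 1e-9)
  expect_equal(r1$beta_int, r2$beta_int, tolerance = 1e-9)

  perm <- sample(nrow(co$genotypes$dosage))
  co2 <- co
  co2$genotypes <- subset_genotypes(co$genotypes, samples = perm)
  co2$covariates <- co$covariates[perm, ]
  co2$phenotypes <- co$phenotypes[perm, ]
  r3 <- batch_test(m, co2, "hdl")
  expect_equal(r1$lrt_stat, r3$lrt_stat, tolerance = 1e-9)
})

test_that("batch testing isolates failures and is deterministic", {
  set.seed(61)
  d <- cbind(vapply(rep(0.35, 4), function(p) rbinom(300, 2, p),
                    numeric(300)), rep(2, 300))
  g <- toy_genotypes(d)
  X <- simulate_covariates(300, seed = 62, sample_ids = sample_ids(g))
  P <- data.frame(sample_id = sample_ids(g),
                  tc = rnorm(300, 5), hdl = rnorm(300, 1.4),
                  ldl = rnorm(300, 3), tg = exp(rnorm(300, 0.4, 0.3)))
  cohort <- list(name = "c1", role = "discovery", genotypes = g,
                 covariates = X, phenotypes = P)
  models <- data.frame(
    snp_a = c("t01", "t02", "t01"), snp_b = c("t02", "t03", "t05"),
    provenance = "mef")
  res <- batch_test(models, cohort, "hdl")
  expect_equal(nrow(res), 3)
  expect_equal(res$status, c("ok", "ok", "monomorphic"))
  res2 <- batch_test(models, cohort, "hdl")
  expect_identical(res, res2)
  # TG must be tested on the log scale
  expect_error(batch_test(models, cohort, "tg"), "log")
  res_lt <- batch_test(models[1, ], cohort, "log_tg")
  expect_equal(res_lt$status, "ok")
})
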