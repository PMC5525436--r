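# The interaction test itself: reduced model
#   y ~ SNP1 + SNP2 + age + BMI + medication + T2D + smoking + sex +
#       PC1..PC10
# versus the full model with the additional multiplicative term
# SNP1*SNP2, compared by a likelihood ratio test on chi-square(1).

#' Ordinary least squares with Gaussian log-likelihood
#'
#' Thin QR-based OLS used by every regression stage. The log-likelihood
#' is the profiled Gaussian one, `-(n/2) (log(2 pi RSS / n) + 1)`.
#' Rank-deficient designs are reported via `status = "collinear"`
#' rather than an error; an exact fit (RSS = 0) is flagged and its
#' log-likelihood guarded at `+Inf`.
#'
#' @param y response vector (no missing values).
#' @param X design matrix including the intercept column.
#' @return list: `coef`, `se`, `rss`, `r2`, `loglik`, `rank`, `n`,
#'   `status` (`"ok"` or `"collinear"`), `exact_fit`.
#' @export
fit_linear <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    return(list(coef = rep(NA_real_, ncol(X)), se = rep(NA_real_, ncol(X)),
                rss = NA_real_, r2 = NA_real_, loglik = NA_real_,
                rank = qr_x$rank, n = n, status = "collinear",
                exact_fit = FALSE))
  }
  coef <- qr.coef(qr_x, y)
  res <- y - X %*% coef
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  exact <- rss < 1e-12 * max(1, tss)
  loglik <- if (exact) Inf else -(n / 2) * (log(2 * pi * rss / n) + 1)
  sigma2 <- rss / (n - qr_x$rank)
  XtX_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(pmax(0, diag(XtX_inv) * sigma2))
  list(coef = as.numeric(coef), se = se, rss = rss, r2 = r2,
       loglik = loglik, rank = qr_x$rank, n = n, status = "ok",
       exact_fit = exact)
}

# Build the covariate matrix for a cohort; returns NULL columns dropped.
covariate_design <- function(X, covariates) {
  as.matrix(X[, covariates, drop = FALSE])
}

#' Likelihood ratio test for a multiplicative SNP-SNP interaction
#'
#' Fits the reduced model (two SNP main effects plus covariates) and the
#' full model (adding the dosage product `g_a * g_b`) on the identical
#' complete-case sample, and compares them with
#' `LRT = n log(RSS_reduced / RSS_full)`, referred to chi-square with one
#' degree of freedom. Reports the interaction coefficient, its standard
#' error, the R-squared of both models and their difference.
#'
#' @param model one-row data.frame with `snp_a`, `snp_b` (and optionally
#'   `provenance`).
#' @param g a `genotype_matrix`
#' @param y trait vector aligned with the samples of `g`.
#' @param X covariate table aligned with `g`.
#' @param covariates covariate column names.
#' @return one-row data.frame (an `InteractionResult`): `snp_a`, `snp_b`,
#'   `provenance`, `n_used`, `beta_a`, `beta_b`, `beta_int`, `se_int`,
#'   `lrt_stat`, `p_lrt`, `r2_full`, `r2_reduced`, `diff_r2`, `status`.
#' @export
lrt_interaction <- function(model, g, y, X,
                            covariates = intersect(default_covariates(),
                                                   names(X))) {
  prov <- if (!is.null(model$provenance)) model$provenance else "unknown"
  base <- data.frame(snp_a = model$snp_a, snp_b = model$snp_b,
                     provenance = prov, n_used = 0L,
                     beta_a = NA_real_, beta_b = NA_real_,
                     beta_int = NA_real_, se_int = NA_real_,
                     lrt_stat = NA_real_, p_lrt = NA_real_,
                     r2_full = NA_real_, r2_reduced = NA_real_,
                     diff_r2 = NA_real_, status = "ok")
  ids <- snp_ids(g)
  if (!model$snp_a %in% ids || !model$snp_b %in% ids) {
    base$status <- "snp_absent"
    return(base)
  }
  ga <- g$dosage[, model$snp_a]
  gb <- g$dosage[, model$snp_b]
  C <- covariate_design(X, covariates)
  use <- !is.na(y) & !is.na(ga) & !is.na(gb) & stats::complete.cases(C)
  n <- sum(use)
  base$n_used <- n
  p_full <- 4 + length(covariates)
  if (n <= p_full) {
    base$status <- "insufficient_n"
    return(base)
  }
  ga <- ga[use]; gb <- gb[use]; yy <- y[use]
  if (stats::var(ga) == 0 || stats::var(gb) == 0) {
    base$status <- "monomorphic"
    return(base)
  }
  Cu <- C[use, , drop = FALSE]
  Xr <- cbind(`(Intercept)` = 1, snp_a = ga, snp_b = gb, Cu)
  Xf <- cbind(Xr, interaction = ga * gb)
  fit_r <- fit_linear(yy, Xr)
  fit_f <- fit_linear(yy, Xf)
  if (fit_r$status != "ok" || fit_f$status != "ok") {
    base$status <- "collinear"
    return(base)
  }
  base$beta_a <- fit_f$coef[2]
  base$beta_b <- fit_f$coef[3]
  base$beta_int <- fit_f$coef[ncol(Xf)]
  base$se_int <- fit_f$se[ncol(Xf)]
  base$r2_full <- fit_f$r2
  base$r2_reduced <- fit_r$r2
  base$diff_r2 <- fit_f$r2 - fit_r$r2
  if (fit_f$exact_fit) {
    lrt <- if (fit_r$exact_fit) 0 else Inf
  } else {
    lrt <- n * log(fit_r$rss / fit_f$rss)
  }
  base$lrt_stat <- max(0, lrt)
  base$p_lrt <- stats::pchisq(base$lrt_stat, df = 1, lower.tail = FALSE)
  base
}

#' Test a batch of SNP-pair models in one cohort
#'
#' One [lrt_interaction()] row per model, in the input order; per-model
#' failures are recorded in `status` and never abort the batch.
#'
#' @param models data.frame of models (`snp_a`, `snp_b`, optional
#'   `provenance`).
#' @param cohort a cohort dataset (list with `genotypes`, `covariates`,
#'   `phenotypes`).
#' @param trait one of `"hdl"`, `"ldl"`, `"tc"`, `"log_tg"`, or any
#'   column of the cohort's phenotype table. `"tg"` is refused: TG is
#'   analyzed on the log scale.
#' @param covariates covariate column names.
#' @return data.frame of `InteractionResult` rows with a leading `trait`
#'   column.
#' @export
batch_test <- function(models, cohort, trait,
                       covariates = intersect(default_covariates(),
                                              names(cohort$covariates))) {
  if (identical(trait, "tg")) {
    stop("test TG on the log scale: use trait = 'log_tg'")
  }
  pheno <- cohort$phenotypes
  if (trait == "log_tg" && !"log_tg" %in% names(pheno)) {
    pheno$log_tg <- log_transform_tg(pheno$tg)
  }
  if (!trait %in% names(pheno)) stop("trait not found: ", trait)
  stopifnot(identical(sample_ids(cohort$genotypes), pheno$sample_id),
            identical(sample_ids(cohort$genotypes),
                      cohort$covariates$sample_id))
  y <- pheno[[trait]]
  rows <- lapply(seq_len(nrow(models)), function(i) {
    lrt_interaction(models[i, , drop = FALSE], cohort$genotypes, y,
                    cohort$covariates, covariates)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- lrt_interaction(data.frame(snp_a = "x", snp_b = "y"),
                           cohort$genotypes, y, cohort$covariates,
                           covariates)[0, ]
  }
  cbind(trait = rep(trait, nrow(out)), out)
}

#' Write an interaction results table as TSV
#' @param results data.frame from [batch_test()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_results_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
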