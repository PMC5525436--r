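# Discovery-phase genotype and sample quality control: call-rate
# filters, Hardy-Weinberg exact test, MAF filter, relatedness removal by
# pi-hat and principal components. The canonical pipeline order is
# SNP call rate -> HWE -> sample call rate -> relatedness -> MAF.

#' SNP call-rate filter
#'
#' Retains SNPs whose fraction of non-missing calls is at least
#' `min_call_rate`.
#'
#' @param g a `genotype_matrix`
#' @param min_call_rate retention threshold in (0, 1\] (default 0.95).
#' @return list with `genotypes` (filtered) and `removed` (SNP IDs).
#' @export
snp_call_rate_filter <- function(g, min_call_rate = 0.95) {
  stopifnot(min_call_rate > 0, min_call_rate <= 1)
  if (ncol(g$dosage) == 0 || nrow(g$dosage) == 0) {
    stop("empty genotype matrix")
  }
  cr <- snp_call_rate(g)
  keep <- cr >= min_call_rate
  list(genotypes = subset_genotypes(g, snps = which(keep)),
       removed = snp_ids(g)[!keep])
}

#' Sample call-rate filter
#'
#' Retains samples whose fraction of non-missing calls is at least
#' `min_call_rate`.
#'
#' @param g a `genotype_matrix`
#' @param min_call_rate retention threshold in (0, 1\] (default 0.90).
#' @return list with `genotypes` and `removed` (sample IDs).
#' @export
sample_call_rate_filter <- function(g, min_call_rate = 0.90) {
  stopifnot(min_call_rate > 0, min_call_rate <= 1)
  if (ncol(g$dosage) == 0 || nrow(g$dosage) == 0) {
    stop("empty genotype matrix")
  }
  cr <- sample_call_rate(g)
  keep <- cr >= min_call_rate
  list(genotypes = subset_genotypes(g, samples = which(keep)),
       removed = sample_ids(g)[!keep])
}

#' Minor-allele-frequency filter
#'
#' MAF is the folded frequency `min(f, 1 - f)` with `f` the mean
#' non-missing dosage over two. SNPs with `MAF >= min_maf` are retained
#' (inclusive boundary). SNPs with zero non-missing calls are removed
#' with a warning.
#'
#' @param g a `genotype_matrix`
#' @param min_maf threshold in \[0, 0.5\] (default 0.05).
#' @return list with `genotypes` and `removed`.
#' @export
maf_filter <- function(g, min_maf = 0.05) {
  stopifnot(min_maf >= 0, min_maf <= 0.5)
  maf <- snp_maf(g)
  nocall <- is.nan(maf)
  if (any(nocall)) {
    warning(sum(nocall), " SNP(s) with zero non-missing calls removed")
  }
  keep <- !nocall & maf >= min_maf
  list(genotypes = subset_genotypes(g, snps = which(keep)),
       removed = snp_ids(g)[!keep])
}

#' Pairwise IBD pi-hat estimation (method of moments)
#'
#' PLINK-style moment estimator: for each sample pair, observed counts of
#' identity-by-state (IBS) 0/1/2 across SNPs complete in both samples are
#' compared with their expectations under IBD states 0/1/2 given the
#' sample allele frequencies, solved sequentially for P(IBD=0), P(IBD=1),
#' P(IBD=2). `pihat = P(IBD=1)/2 + P(IBD=2)`, clamped to \[0, 1\]; the
#' unclamped value is kept in `pihat_raw`.
#'
#' @param g a `genotype_matrix` (>= 2 samples; MAF-filtered input
#'   recommended).
#' @return data.frame `id1`, `id2`, `pihat`, `pihat_raw`, `n_snps`.
#' @export
estimate_ibd_pihat <- function(g) {
  d <- g$dosage
  n <- nrow(d)
  if (n < 2) stop("need at least 2 samples")
  p <- colMeans(d, na.rm = TRUE) / 2   # ALT allele frequency
  poly <- !is.na(p) & p > 0 & p < 1
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  if (ncol(d) < 50) {
    warning("fewer than 50 informative SNPs; pi-hat estimates unstable")
  }
  q <- 1 - p
  # per-SNP expected IBS-state probabilities under each IBD state
  e0_ibd0 <- 2 * p^2 * q^2
  e1_ibd0 <- 4 * p^3 * q + 4 * p * q^3
  e2_ibd0 <- p^4 + q^4 + 4 * p^2 * q^2
  e1_ibd1 <- 2 * p^2 * q + 2 * p * q^2
  e2_ibd1 <- 1 - e1_ibd1

  ids <- rownames(d)
  pairs <- utils::combn(n, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    use <- !is.na(d[i, ]) & !is.na(d[j, ])
    diff <- abs(d[i, use] - d[j, use])
    L <- sum(use)
    N0 <- sum(diff == 2); N1 <- sum(diff == 1); N2 <- sum(diff == 0)
    s0_0 <- sum(e0_ibd0[use]); s1_0 <- sum(e1_ibd0[use])
    s2_0 <- sum(e2_ibd0[use]); s1_1 <- sum(e1_ibd1[use])
    s2_1 <- sum(e2_ibd1[use])
    P0 <- N0 / s0_0
    P1 <- (N1 - P0 * s1_0) / s1_1
    P2 <- (N2 - P0 * s2_0 - P1 * s2_1) / L
    raw <- P1 / 2 + P2
    data.frame(id1 = ids[i], id2 = ids[j],
               pihat = min(1, max(0, raw)), pihat_raw = raw, n_snps = L)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Remove related samples by pi-hat
#'
#' Greedy removal: while any pair exceeds the threshold, drop the sample
#' participating in the most over-threshold pairs (ties broken by lower
#' call rate, then by lexicographically smaller sample ID), so exactly
#' one member of an isolated related pair is removed and clusters are
#' broken near-minimally.
#'
#' @param g a `genotype_matrix`
#' @param pihat_table output of [estimate_ibd_pihat()] covering all pairs.
#' @param threshold pi-hat above which a pair counts as related
#'   (default 0.3, strict `>`).
#' @return list with `genotypes` and `removed` (sample IDs).
#' @export
remove_related <- function(g, pihat_table, threshold = 0.3) {
  over <- pihat_table[pihat_table$pihat > threshold, c("id1", "id2")]
  cr <- sample_call_rate(g)
  removed <- character(0)
  while (nrow(over) > 0) {
    tab <- table(c(over$id1, over$id2))
    cand <- names(tab)[tab == max(tab)]
    if (length(cand) > 1) {
      cand_cr <- cr[cand]
      cand <- cand[cand_cr == min(cand_cr)]
      cand <- sort(cand)[1]
    }
    removed <- c(removed, cand)
    over <- over[over$id1 != cand & over$id2 != cand, , drop = FALSE]
  }
  keep <- setdiff(sample_ids(g), removed)
  list(genotypes = subset_genotypes(g, samples = keep), removed = removed)
}

#' Principal components of the genotype matrix
#'
#' Dosages are mean-imputed, centered and scaled to unit variance per SNP
#' (zero-variance SNPs dropped); scores are the first `k` left singular
#' vectors scaled by their singular values. Sign convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param g a `genotype_matrix`
#' @param k number of components (default 10; must be
#'   `< min(n_samples, n_snps)`).
#' @return matrix of scores (`n x k`, columns `PC1..PCk`) with
#'   attributes `loadings` and `var_explained`.
#' @export
compute_pcs <- function(g, k = 10) {
  d <- g$dosage
  cm <- colMeans(d, na.rm = TRUE)
  for (j in seq_len(ncol(d))) d[is.na(d[, j]), j] <- cm[j]
  sds <- apply(d, 2, stats::sd)
  d <- d[, sds > 0, drop = FALSE]
  if (k >= min(nrow(d), ncol(d))) {
    stop("k must be smaller than min(n_samples, n_snps)")
  }
  z <- scale(d)
  sv <- svd(z, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(rownames(d), paste0("PC", seq_len(k)))
  attr(scores, "loadings") <- loadings
  attr(scores, "var_explained") <- sv$d[seq_len(k)]^2 / sum(sv$d^2)
  scores
}

#' Run the full genotype QC pipeline
#'
#' Applies, in the fixed order logged in the report: SNP call rate,
#' Hardy-Weinberg exact test, sample call rate, relatedness removal, and
#' the (per-analysis) MAF filter. Any step can be dropped via `steps`;
#' MAF is computed after relatedness removal.
#'
#' @param g a `genotype_matrix`
#' @param snp_call_rate,sample_call_rate retention thresholds.
#' @param hwe_p exact-test p-value below which a SNP is removed
#'   (default 1e-7).
#' @param pihat_threshold relatedness threshold (default 0.3).
#' @param min_maf MAF threshold (default 0.05).
#' @param steps subset of
#'   `c("snp_callrate", "hwe", "sample_callrate", "relatedness", "maf")`.
#' @return list with `genotypes` and `report` (class `qc_report`): the
#'   thresholds, per-step removed IDs and the surviving SNP/sample IDs,
#'   sufficient to replay the QC bit-exactly via [apply_qc_report()].
#' @export
run_genotype_qc <- function(g,
                            snp_call_rate = 0.95,
                            hwe_p = 1e-7,
                            sample_call_rate = 0.90,
                            pihat_threshold = 0.3,
                            min_maf = 0.05,
                            steps = c("snp_callrate", "hwe",
                                      "sample_callrate", "relatedness",
                                      "maf")) {
  steps <- match.arg(steps, several.ok = TRUE)
  removed <- list()
  if ("snp_callrate" %in% steps) {
    res <- snp_call_rate_filter(g, snp_call_rate)
    removed$snp_callrate <- res$removed
    g <- res$genotypes
  }
  if ("hwe" %in% steps) {
    p <- hwe_test_genotypes(g)
    drop <- !is.na(p) & p < hwe_p
    removed$hwe <- snp_ids(g)[drop]
    g <- subset_genotypes(g, snps = which(!drop))
  }
  if ("sample_callrate" %in% steps) {
    res <- sample_call_rate_filter(g, sample_call_rate)
    removed$sample_callrate <- res$removed
    g <- res$genotypes
  }
  if ("relatedness" %in% steps) {
    ph <- estimate_ibd_pihat(g)
    res <- remove_related(g, ph, pihat_threshold)
    removed$relatedness <- res$removed
    g <- res$genotypes
  }
  if ("maf" %in% steps) {
    res <- maf_filter(g, min_maf)
    removed$maf <- res$removed
    g <- res$genotypes
  }
  report <- structure(list(
    steps = steps,
    thresholds = c(snp_call_rate = snp_call_rate, hwe_p = hwe_p,
                   sample_call_rate = sample_call_rate,
                   pihat = pihat_threshold, maf = min_maf),
    removed = removed,
    counts = vapply(removed, length, integer(1)),
    snps_retained = snp_ids(g),
    samples_retained = sample_ids(g),
    maf_after_relatedness = TRUE
  ), class = "qc_report")
  list(genotypes = g, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("genotype QC report\n  steps:", paste(x$steps, collapse = " -> "),
      "\n")
  for (nm in names(x$removed)) {
    cat(sprintf("  %-16s removed %d\n", nm, length(x$removed[[nm]])))
  }
  cat(sprintf("  retained: %d samples x %d SNPs\n",
              length(x$samples_retained), length(x$snps_retained)))
  invisible(x)
}

#' Replay a QC report on its input
#'
#' Subsets the input matrix to the report's surviving sample and SNP IDs,
#' reproducing the QC output bit-exactly.
#'
#' @param g the original (pre-QC) `genotype_matrix`.
#' @param report a `qc_report`.
#' @return the filtered `genotype_matrix`.
#' @export
apply_qc_report <- function(g, report) {
  subset_genotypes(g, samples = report$samples_retained,
                   snps = report$snps_retained)
}
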