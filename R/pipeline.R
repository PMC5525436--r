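# End-to-end orchestration: QC the merged discovery set, generate
# candidate models (main-effect-filter or knowledge arm), run the
# interaction LRT, select models, build proxy models, test them in every
# replication cohort, and collapse the results into signals.

# Restrict a cohort dataset to the samples/SNPs surviving QC, keeping
# covariate and phenotype rows aligned.
qc_cohort <- function(cohort, ...) {
  qc <- run_genotype_qc(cohort$genotypes, ...)
  ids <- sample_ids(qc$genotypes)
  cohort$genotypes <- qc$genotypes
  cohort$covariates <- cohort$covariates[
    match(ids, cohort$covariates$sample_id), , drop = FALSE]
  cohort$phenotypes <- cohort$phenotypes[
    match(ids, cohort$phenotypes$sample_id), , drop = FALSE]
  cohort$qc_report <- qc$report
  cohort
}

#' Run the two-arm discovery + replication pipeline on a study
#'
#' Convenience driver over the module functions. Discovery cohorts are
#' merged, QC'd and phenotype-prepped; candidate models come from the
#' requested arm; the interaction LRT is run; models passing the
#' discovery threshold are expanded with proxy models (SNPs in high LD
#' with the originals, found in the discovery data) and tested in each
#' replication cohort; signals are collapsed under the Bonferroni-like
#' replication threshold.
#'
#' @param study output of [simulate_study()], or any list with a
#'   `cohorts` element of cohort datasets carrying `role` flags.
#' @param trait `"hdl"`, `"ldl"`, `"tc"` or `"log_tg"`.
#' @param arm `"mef"` (main-effect filter + exhaustive pairing, with LD
#'   pruning) or `"knowledge"` (gene-pair models, no pruning).
#' @param annotation,kb gene annotation and knowledge table (knowledge
#'   arm only; default: one gene per simulated LD block).
#' @param mef_p marginal main-effect threshold (default 0.001).
#' @param prune_r2 LD prune threshold for the MEF arm (default 0.6).
#' @param min_sources knowledge-source threshold (default 5).
#' @param discovery_p discovery LRT selection threshold (default 0.001).
#' @param proxy_r2 proxy LD threshold (default 0.8).
#' @param alpha family-wise level for the replication threshold.
#' @param qc_steps QC steps to run per cohort (pairwise relatedness is
#'   excluded by default: simulated samples are unrelated and the pair
#'   scan is quadratic in n; include `"relatedness"` to enable it).
#' @param covariates covariate column names.
#' @return list: `discovery` (QC'd dataset), `scan` (MEF arm),
#'   `models`, `results`, `selected`, `proxies`, `threshold`,
#'   `per_cohort`, `signals`, `summary`.
#' @export
run_gwis_pipeline <- function(study, trait, arm = c("mef", "knowledge"),
                              annotation = NULL, kb = NULL,
                              mef_p = 0.001, prune_r2 = 0.6,
                              min_sources = 5, discovery_p = 0.001,
                              proxy_r2 = 0.8, alpha = 0.05,
                              qc_steps = c("snp_callrate", "hwe",
                                           "sample_callrate", "maf"),
                              covariates = NULL) {
  arm <- match.arg(arm)
  roles <- vapply(study$cohorts, `[[`, "", "role")
  disc <- merge_cohorts(study$cohorts[roles == "discovery"])
  reps <- study$cohorts[roles == "replication"]

  disc <- qc_cohort(disc, steps = qc_steps)
  reps <- lapply(reps, qc_cohort, steps = qc_steps)
  disc$phenotypes <- prep_lipid_panel(disc$phenotypes, derive_ldl = FALSE)
  reps <- lapply(reps, function(co) {
    co$phenotypes <- prep_lipid_panel(co$phenotypes, derive_ldl = FALSE)
    co
  })
  if (is.null(covariates)) {
    covariates <- intersect(default_covariates(), names(disc$covariates))
  }
  y <- disc$phenotypes[[trait]]

  scan <- NULL
  if (arm == "mef") {
    retained <- ld_prune(disc$genotypes, threshold = prune_r2)
    scan <- main_effect_scan(disc$genotypes, y, disc$covariates,
                             covariates)
    models <- main_effect_filter_models(scan, threshold = mef_p,
                                        retained_snps = retained)
  } else {
    if (is.null(annotation)) {
      annotation <- simulate_gene_annotation(disc$genotypes)
    }
    if (is.null(kb)) stop("knowledge arm requires a knowledge base")
    map <- map_snps_to_genes(disc$genotypes$snps, annotation)
    models <- knowledge_models(kb, map, min_sources = min_sources)
  }

  out <- list(discovery = disc, scan = scan, models = models,
              results = NULL, selected = NULL, proxies = NULL,
              threshold = NULL, per_cohort = list(),
              signals = NULL, summary = NULL)
  if (nrow(models) == 0) {
    out$selected <- models
    return(out)
  }
  results <- batch_test(models, disc, trait, covariates)
  selected <- select_discovery_models(results, p_threshold = discovery_p)
  out$results <- results
  out$selected <- selected
  if (nrow(selected) == 0 || length(reps) == 0) return(out)

  proxies <- do.call(rbind, lapply(seq_len(nrow(selected)), function(i) {
    m <- selected[i, ]
    proxy_models(m,
                 find_proxies(disc$genotypes, m$snp_a, proxy_r2),
                 find_proxies(disc$genotypes, m$snp_b, proxy_r2))
  }))
  if (is.null(proxies)) {
    proxies <- data.frame(snp_a = character(), snp_b = character(),
                          provenance = character())
  }
  thr <- replication_threshold(nrow(selected), n_cohorts = length(reps),
                               alpha = alpha)
  per_cohort <- lapply(reps, function(co) {
    test_models_in_cohort(selected, proxies, co, trait, covariates)
  })
  names(per_cohort) <- vapply(reps, `[[`, "", "name")
  signals <- collapse_signals(selected, per_cohort, thr$threshold)
  out$proxies <- proxies
  out$threshold <- thr
  out$per_cohort <- per_cohort
  out$signals <- signals
  out$summary <- summarize_replication(signals)
  out
}
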