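# Multi-cohort replication: discovery selection, Bonferroni-like
# per-arm thresholds, per-cohort testing of original + proxy models,
# collapsing of LD signals (an original model and its proxies count once
# per cohort) and the summary table.

#' Select discovery models for replication testing
#'
#' Models with `status == "ok"` and `p_lrt` strictly below the threshold,
#' ranked ascending by p-value (ties broken by canonical model key).
#' Optionally the threshold can be Bonferroni-adjusted for the number of
#' models tested instead of the flat default.
#'
#' @param results discovery results from [batch_test()].
#' @param p_threshold flat selection threshold (default 0.001).
#' @param bonferroni if `TRUE`, use `alpha / nrow(results)` instead.
#' @param alpha family-wise level for the Bonferroni option.
#' @return the selected rows with a `disc_rank` column.
#' @export
select_discovery_models <- function(results, p_threshold = 0.001,
                                    bonferroni = FALSE, alpha = 0.05) {
  thr <- if (bonferroni) alpha / nrow(results) else p_threshold
  ok <- results$status == "ok" & !is.na(results$p_lrt) &
    results$p_lrt < thr
  sel <- results[ok, , drop = FALSE]
  key <- model_key(sel)
  sel <- sel[order(sel$p_lrt, key), , drop = FALSE]
  sel$disc_rank <- seq_len(nrow(sel))
  rownames(sel) <- NULL
  sel
}

#' Bonferroni-like replication threshold
#'
#' `alpha / (n_original_models * n_cohorts)`: the family-wise level is
#' split over the original (non-proxy) models selected for replication
#' and over the replication cohorts. The display value rounds to one
#' significant figure, the convention used when quoting such thresholds;
#' comparisons always use the unrounded value.
#'
#' @param n_original_models count of original models selected (>= 1).
#' @param n_cohorts number of replication cohorts (default 10).
#' @param alpha family-wise level (default 0.05).
#' @return list with `threshold` (exact), `display` (1-significant-figure
#'   numeric) and `display_string`.
#' @export
#' @examples
#' replication_threshold(156, 10)  # 3.205e-05, displayed 0.00003
#' replication_threshold(22, 10)   # 2.27e-04, displayed 0.0002
replication_threshold <- function(n_original_models, n_cohorts = 10,
                                  alpha = 0.05) {
  if (n_original_models < 1 || n_cohorts < 1) {
    stop("model and cohort counts must be >= 1")
  }
  thr <- alpha / (n_original_models * n_cohorts)
  disp <- signif(thr, 1)
  list(threshold = thr, display = disp,
       display_string = format(disp, scientific = FALSE, trim = TRUE))
}

#' Test original and proxy models in one replication cohort
#'
#' Runs [batch_test()] over the stacked original + proxy model list.
#' Models whose SNPs are absent from the cohort's genotypes are not
#' testable there (typical for proxy SNPs missing from an array) and are
#' kept as rows with `status = "snp_absent"`.
#'
#' @param models original models (data.frame).
#' @param proxies proxy models (data.frame, may be empty).
#' @param cohort a cohort dataset.
#' @param trait trait name as in [batch_test()].
#' @param covariates covariate column names.
#' @return results data.frame over originals then proxies.
#' @export
test_models_in_cohort <- function(models, proxies, cohort, trait,
                                  covariates =
                                    intersect(default_covariates(),
                                              names(cohort$covariates))) {
  cols <- c("snp_a", "snp_b", "provenance")
  all_models <- rbind(models[, cols, drop = FALSE],
                      proxies[, cols, drop = FALSE])
  res <- batch_test(all_models, cohort, trait, covariates)
  n_absent <- sum(res$status == "snp_absent")
  if (n_absent > 0) {
    message(n_absent, " model(s) skipped in ", cohort$name,
            ": SNP absent from the cohort")
  }
  res
}

#' Collapse original + proxy models into replication signals
#'
#' Each selected original model and its proxy models form one LD signal.
#' A cohort replicates the signal if *any* member attains
#' `p_lrt < threshold` there; even if the original and several proxies
#' all pass, the signal counts once for that cohort. Per cohort, the
#' member with the lowest p-value is reported as the lead result, and
#' the sign of its interaction beta is compared with the discovery sign.
#'
#' @param discovery_selection output of [select_discovery_models()].
#' @param per_cohort_results named list: cohort name -> results from
#'   [test_models_in_cohort()]. Proxy rows must carry
#'   `provenance = "proxy-of:<original key>"`; a proxy referencing no
#'   selected original is an error.
#' @param threshold replication p-value threshold (unrounded).
#' @return data.frame, one row per signal: discovery stats, replicating
#'   cohorts (comma-joined), `n_replicating`, lead replication beta /
#'   p-value / cohort, per-cohort direction concordance and
#'   `threshold_used`.
#' @export
collapse_signals <- function(discovery_selection, per_cohort_results,
                             threshold) {
  orig_keys <- model_key(discovery_selection)
  for (res in per_cohort_results) {
    prox <- grepl("^proxy-of:", res$provenance)
    refs <- sub("^proxy-of:", "", res$provenance[prox])
    if (!all(refs %in% orig_keys)) {
      stop("orphan proxy model: no matching original in the selection")
    }
  }
  rows <- lapply(seq_len(nrow(discovery_selection)), function(i) {
    key <- orig_keys[i]
    disc <- discovery_selection[i, ]
    rep_cohorts <- character(0)
    concord <- logical(0)
    best_p <- NA_real_; best_beta <- NA_real_; best_cohort <- NA_character_
    for (cname in names(per_cohort_results)) {
      res <- per_cohort_results[[cname]]
      member <- (model_key(res) == key &
                   !grepl("^proxy-of:", res$provenance)) |
        res$provenance == paste0("proxy-of:", key)
      cand <- res[member & res$status == "ok" & !is.na(res$p_lrt), ,
                  drop = FALSE]
      if (nrow(cand) == 0) next
      lead <- cand[which.min(cand$p_lrt), ]
      if (lead$p_lrt < threshold) {
        rep_cohorts <- c(rep_cohorts, cname)
        concord <- c(concord,
                     sign(lead$beta_int) == sign(disc$beta_int))
        if (is.na(best_p) || lead$p_lrt < best_p) {
          best_p <- lead$p_lrt
          best_beta <- lead$beta_int
          best_cohort <- cname
        }
      }
    }
    data.frame(
      signal_id = key,
      snp_a = disc$snp_a, snp_b = disc$snp_b,
      disc_rank = disc$disc_rank,
      disc_beta = disc$beta_int, disc_p = disc$p_lrt,
      n_replicating = length(rep_cohorts),
      replicating_cohorts = paste(rep_cohorts, collapse = ","),
      best_rep_beta = best_beta, best_rep_p = best_p,
      best_rep_cohort = best_cohort,
      direction_concordant = paste(concord, collapse = ","),
      threshold_used = threshold
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(signal_id = character(), snp_a = character(),
                      snp_b = character(), disc_rank = integer(),
                      disc_beta = numeric(), disc_p = numeric(),
                      n_replicating = integer(),
                      replicating_cohorts = character(),
                      best_rep_beta = numeric(), best_rep_p = numeric(),
                      best_rep_cohort = character(),
                      direction_concordant = character(),
                      threshold_used = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Replication summary table
#'
#' Filters signals to those replicating in at least `min_cohorts`
#' cohorts and returns the reporting schema sorted by discovery rank:
#' rank, SNPs, discovery beta and LRT p, lead replication beta and LRT
#' p, and the replicating cohort labels.
#'
#' @param signals output of [collapse_signals()].
#' @param min_cohorts minimum number of replicating cohorts (default 1).
#' @return summary data.frame (empty but with a valid header when
#'   nothing replicates).
#' @export
summarize_replication <- function(signals, min_cohorts = 1) {
  keep <- signals$n_replicating >= min_cohorts
  out <- signals[keep, c("disc_rank", "snp_a", "snp_b", "disc_beta",
                         "disc_p", "best_rep_beta", "best_rep_p",
                         "replicating_cohorts", "n_replicating"), ]
  out <- out[order(out$disc_rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}
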