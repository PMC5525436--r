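# Candidate SNP-SNP model generation: the main-effect-filter arm
# (marginal scan + exhaustive pairing of passing SNPs) and the
# knowledge-driven arm (gene pairs supported by curated sources, SNPs
# mapped to genes with a +/- 50 kb window).

#' Number of k-way interaction models among n SNPs
#'
#' The combinatorial burden of exhaustive interaction testing:
#' `choose(n, k)` models (e.g. 1000 SNPs give 499,500 two-way and
#' 166,167,000 three-way models).
#'
#' @param n_snps number of SNPs.
#' @param order interaction order (2 = pairwise).
#' @return model count.
#' @export
count_interaction_models <- function(n_snps, order = 2) {
  stopifnot(n_snps >= 0, order >= 1)
  choose(n_snps, order)
}

#' Marginal (main-effect) scan
#'
#' Per SNP, fits the linear model `y ~ dosage + covariates` on complete
#' cases and returns the two-sided p-value of the dosage coefficient.
#' Monomorphic SNPs (on the complete cases) get `NA` with a warning.
#'
#' @param g a `genotype_matrix`
#' @param y named or positional trait vector aligned with the samples.
#' @param X covariate table (`sample_id` + covariate columns).
#' @param covariates covariate column names (default
#'   [default_covariates()] intersected with `X`).
#' @return data.frame `snp_id`, `beta`, `se`, `p`, `n_used`.
#' @export
main_effect_scan <- function(g, y, X,
                             covariates = intersect(default_covariates(),
                                                    names(X))) {
  stopifnot(length(y) == nrow(g$dosage),
            identical(sample_ids(g), X$sample_id))
  C <- as.matrix(X[, covariates, drop = FALSE])
  n_mono <- 0L
  out <- lapply(seq_len(ncol(g$dosage)), function(j) {
    gj <- g$dosage[, j]
    use <- !is.na(y) & !is.na(gj) & stats::complete.cases(C)
    res <- list(beta = NA_real_, se = NA_real_, p = NA_real_,
                n_used = sum(use))
    if (sum(use) > length(covariates) + 2 &&
        stats::var(gj[use]) > 0) {
      M <- cbind(1, gj[use], C[use, , drop = FALSE])
      fit <- fit_linear(y[use], M)
      if (fit$status == "ok") {
        res$beta <- fit$coef[2]
        res$se <- fit$se[2]
        res$p <- 2 * stats::pt(abs(fit$coef[2] / fit$se[2]),
                               df = fit$n - fit$rank, lower.tail = FALSE)
      }
    } else if (sum(use) > 0 && stats::var(gj[use]) == 0) {
      n_mono <<- n_mono + 1L
    }
    res
  })
  if (n_mono > 0) warning(n_mono, " monomorphic SNP(s): p set to NA")
  data.frame(snp_id = snp_ids(g),
             beta = vapply(out, `[[`, 0, "beta"),
             se = vapply(out, `[[`, 0, "se"),
             p = vapply(out, `[[`, 0, "p"),
             n_used = vapply(out, `[[`, 0L, "n_used"))
}

#' Exhaustive SNP-pair models from the main-effect filter
#'
#' All `C(m, 2)` unordered pairs of the SNPs that pass the marginal
#' p-value threshold (strict `<`, default 0.001) and are in the
#' LD-pruned retained set.
#'
#' @param pvals data.frame from [main_effect_scan()] (needs `snp_id`,
#'   `p`).
#' @param threshold marginal significance threshold.
#' @param retained_snps IDs surviving LD pruning; pairs are drawn only
#'   from these.
#' @return data.frame `snp_a`, `snp_b`, `provenance` (canonical order).
#' @export
main_effect_filter_models <- function(pvals, threshold = 0.001,
                                      retained_snps = pvals$snp_id) {
  pass <- pvals$snp_id[!is.na(pvals$p) & pvals$p < threshold &
                         pvals$snp_id %in% retained_snps]
  if (length(pass) < 2) {
    if (length(pass) < 2) warning("fewer than 2 SNPs pass the filter; ",
                                  "no models generated")
    return(data.frame(snp_a = character(), snp_b = character(),
                      provenance = character()))
  }
  pairs <- utils::combn(sort(pass), 2)
  data.frame(snp_a = pairs[1, ], snp_b = pairs[2, ],
             provenance = "main_effect_filter")
}

#' Map SNPs to genes with a flanking window
#'
#' A SNP is assigned to every gene whose interval, extended by
#' `window_bp` on both sides, contains its position. Gene intervals are
#' 0-based half-open, so the inclusion test is
#' `start - window <= pos < end + window`: a SNP exactly 50,000 bp
#' upstream of the gene start is mapped, one at 50,001 bp is not. SNPs
#' on chromosomes absent from the annotation stay unmapped.
#'
#' @param snps data.frame with `snp_id`, `chrom`, `pos`.
#' @param annotation gene annotation (`gene`, `chrom`, `start`, `end`).
#' @param window_bp flank size (default 50,000).
#' @return named list: SNP ID -> character vector of genes (possibly
#'   empty).
#' @export
map_snps_to_genes <- function(snps, annotation, window_bp = 50000) {
  validate_gene_annotation(annotation)
  out <- lapply(seq_len(nrow(snps)), function(i) {
    hit <- annotation$chrom == snps$chrom[i] &
      annotation$start - window_bp <= snps$pos[i] &
      snps$pos[i] < annotation$end + window_bp
    annotation$gene[hit]
  })
  names(out) <- snps$snp_id
  out
}

# distinct-source count per canonical gene pair
knowledge_pair_scores <- function(kb) {
  kb <- canonicalize_knowledge_base(kb)
  key <- paste(kb$gene1, kb$gene2, sep = "|")
  agg <- tapply(kb$source, key, function(s) length(unique(s)))
  data.frame(gene1 = sub("\\|.*", "", names(agg)),
             gene2 = sub(".*\\|", "", names(agg)),
             n_sources = as.integer(agg), row.names = NULL)
}

#' Knowledge-driven SNP-pair models
#'
#' For every unordered gene pair supported by at least `min_sources`
#' distinct knowledge sources, emits all SNP pairs with one SNP mapped
#' to each gene. SNPs mapping to both genes of a pair are excluded (the
#' arm exists to pair SNPs in *different* genes), and duplicate SNP
#' pairs arising from different gene pairs are deduplicated by canonical
#' key. No LD pruning is applied in this arm.
#'
#' @param kb knowledge table (`gene1`, `gene2`, `source`).
#' @param snp_gene_map output of [map_snps_to_genes()].
#' @param min_sources inclusion threshold (default 5, `>=`).
#' @return data.frame `snp_a`, `snp_b`, `provenance`, `gene_a`, `gene_b`,
#'   `n_sources`.
#' @export
knowledge_models <- function(kb, snp_gene_map, min_sources = 5) {
  empty <- data.frame(snp_a = character(), snp_b = character(),
                      provenance = character(), gene_a = character(),
                      gene_b = character(), n_sources = integer())
  if (nrow(kb) == 0) return(empty)
  scores <- knowledge_pair_scores(kb)
  scores <- scores[scores$n_sources >= min_sources, , drop = FALSE]
  if (nrow(scores) == 0) return(empty)
  # invert the SNP->genes map
  gene_snps <- list()
  for (s in names(snp_gene_map)) {
    for (gn in snp_gene_map[[s]]) {
      gene_snps[[gn]] <- c(gene_snps[[gn]], s)
    }
  }
  rows <- lapply(seq_len(nrow(scores)), function(i) {
    ga <- scores$gene1[i]; gb <- scores$gene2[i]
    sa <- gene_snps[[ga]]; sb <- gene_snps[[gb]]
    if (is.null(sa) || is.null(sb)) return(NULL)
    shared <- intersect(sa, sb)      # SNPs mapping to both genes
    sa <- setdiff(sa, shared); sb <- setdiff(sb, shared)
    if (!length(sa) || !length(sb)) return(NULL)
    grid <- expand.grid(a = sa, b = sb, stringsAsFactors = FALSE)
    grid <- grid[grid$a != grid$b, , drop = FALSE]
    if (!nrow(grid)) return(NULL)
    data.frame(snp_a = pmin(grid$a, grid$b),
               snp_b = pmax(grid$a, grid$b),
               provenance = "knowledge", gene_a = ga, gene_b = gb,
               n_sources = scores$n_sources[i])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[!duplicated(paste(out$snp_a, out$snp_b, sep = "|")), ,
             drop = FALSE]
  out <- out[order(out$snp_a, out$snp_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
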