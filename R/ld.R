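# Linkage-disequilibrium utilities on unphased dosage data: composite
# (dosage-correlation) r2, greedy pruning, proxy discovery and
# signal-set grouping.

#' Pairwise r-squared between two dosage vectors
#'
#' Squared Pearson correlation of additive dosages over samples complete
#' in both SNPs (composite LD; phase-free, invariant to allele flips
#' `g -> 2 - g`). Undefined when either SNP is monomorphic on the
#' complete pairs: returned as `NA` with a warning.
#'
#' @param g1,g2 dosage vectors of equal length.
#' @return r-squared in \[0, 1\], or `NA`.
#' @export
pairwise_r2 <- function(g1, g2) {
  use <- !is.na(g1) & !is.na(g2)
  if (sum(use) < 2) stop("need at least 2 complete pairs")
  v1 <- stats::var(g1[use]); v2 <- stats::var(g2[use])
  if (v1 == 0 || v2 == 0) {
    warning("monomorphic SNP on complete pairs; r2 undefined")
    return(NA_real_)
  }
  stats::cor(g1[use], g2[use])^2
}

#' Full pairwise LD matrix
#'
#' @param g a `genotype_matrix`
#' @return object of class `ld_matrix`: list with `snp_ids`, `r2`
#'   (symmetric, unit diagonal for polymorphic SNPs, `NA` where
#'   undefined) and `n_pairs` (complete-pair counts).
#' @export
ld_matrix <- function(g) {
  d <- g$dosage
  r <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))
  r2 <- r^2
  r2[r2 > 1] <- 1
  obs <- !is.na(d)
  n_pairs <- crossprod(obs)
  structure(list(snp_ids = snp_ids(g), r2 = r2, n_pairs = n_pairs),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  off <- x$r2[upper.tri(x$r2)]
  cat(sprintf("ld_matrix: %d SNPs, mean off-diagonal r2 = %.4f\n",
              length(x$snp_ids), mean(off, na.rm = TRUE)))
  invisible(x)
}

#' Greedy LD pruning
#'
#' Scans SNPs in order (default: genomic position, ties keeping the
#' higher-MAF SNP first) and removes any SNP whose r-squared with an
#' already-retained SNP exceeds `threshold`. The retained set is
#' guaranteed to contain no pair with r-squared above the threshold;
#' this guarantee is asserted on every run.
#'
#' @param g a `genotype_matrix`
#' @param threshold prune threshold (default 0.6, strict `>` removal).
#' @param order optional explicit SNP-ID ordering overriding the default.
#' @return character vector of retained SNP IDs.
#' @export
ld_prune <- function(g, threshold = 0.6, order = NULL) {
  ids <- snp_ids(g)
  if (is.null(order)) {
    maf <- snp_maf(g)
    ord <- order(g$snps$chrom, g$snps$pos, -maf)
    order <- ids[ord]
  }
  stopifnot(setequal(order, ids))
  ld <- ld_matrix(g)
  r2 <- ld$r2[order, order, drop = FALSE]
  kept <- character(0)
  for (s in order) {
    if (length(kept) == 0) { kept <- s; next }
    worst <- suppressWarnings(max(r2[s, kept], na.rm = TRUE))
    if (!is.finite(worst) || worst <= threshold) kept <- c(kept, s)
  }
  check <- r2[kept, kept, drop = FALSE]
  diag(check) <- 0
  stopifnot(max(check, na.rm = TRUE) <= threshold + 1e-12)
  kept[match(ids[ids %in% kept], kept)]
}

#' Find proxy SNPs in high LD with a model SNP
#'
#' Returns every other SNP whose r-squared with `snp` strictly exceeds
#' `threshold` (default 0.8), computed from the supplied genotype data.
#'
#' @param g a `genotype_matrix`
#' @param snp SNP ID present in `g`.
#' @param threshold proxy threshold (strict `>`).
#' @return character vector of proxy SNP IDs (possibly empty).
#' @export
find_proxies <- function(g, snp, threshold = 0.8) {
  ids <- snp_ids(g)
  if (!snp %in% ids) stop("unknown SNP: ", snp)
  r2 <- suppressWarnings(
    stats::cor(g$dosage, g$dosage[, snp], use = "pairwise.complete.obs")^2
  )[, 1]
  out <- ids[!is.na(r2) & r2 > threshold & ids != snp]
  out
}

#' Expand a SNP-pair model into proxy models
#'
#' Takes the Cartesian product of `{a} + proxies_a` and
#' `{b} + proxies_b`, drops the original pair and any degenerate pair
#' with identical members, and tags each result `proxy-of:<original>`.
#'
#' @param model one-row data.frame with `snp_a`, `snp_b` (a
#'   `SnpPairModel` row).
#' @param proxies_a,proxies_b proxy ID vectors for each side.
#' @return data.frame of proxy models (`snp_a`, `snp_b`, `provenance`),
#'   canonically ordered and deduplicated.
#' @export
proxy_models <- function(model, proxies_a, proxies_b) {
  a <- model$snp_a; b <- model$snp_b
  if (a == b) stop("degenerate model: snp_a == snp_b")
  grid <- expand.grid(snp_a = unique(c(a, proxies_a)),
                      snp_b = unique(c(b, proxies_b)),
                      stringsAsFactors = FALSE)
  grid <- grid[grid$snp_a != grid$snp_b, , drop = FALSE]
  key <- paste(pmin(grid$snp_a, grid$snp_b), pmax(grid$snp_a, grid$snp_b))
  orig_key <- paste(min(a, b), max(a, b))
  grid <- grid[key != orig_key & !duplicated(key), , drop = FALSE]
  key <- key[key != orig_key]
  if (nrow(grid) == 0) {
    return(data.frame(snp_a = character(), snp_b = character(),
                      provenance = character()))
  }
  out <- data.frame(
    snp_a = pmin(grid$snp_a, grid$snp_b),
    snp_b = pmax(grid$snp_a, grid$snp_b),
    provenance = paste0("proxy-of:", model_key(model))
  )
  rownames(out) <- NULL
  out
}

# canonical "snpA|snpB" key for a one-row model
model_key <- function(model) {
  paste(pmin(model$snp_a, model$snp_b), pmax(model$snp_a, model$snp_b),
        sep = "|")
}

#' Group SNPs into LD signal sets
#'
#' Single-linkage connected components of the graph whose edges join
#' SNPs with r-squared strictly above `threshold` (default 0.1, the
#' conventional bound below which model SNPs are treated as
#' uncorrelated). Optionally checks, for a table of SNP-pair models,
#' whether the two SNPs of any model fall in the same set.
#'
#' @param snps SNP IDs to partition.
#' @param ld an `ld_matrix` covering `snps`.
#' @param threshold edge threshold (strict `>`).
#' @param models optional data.frame with `snp_a`, `snp_b`.
#' @return list with `sets` (named integer vector: SNP -> set index) and,
#'   when `models` is given, `within_model_correlated` (logical per row).
#' @export
signal_sets <- function(snps, ld, threshold = 0.1, models = NULL) {
  stopifnot(all(snps %in% ld$snp_ids))
  r2 <- ld$r2[snps, snps, drop = FALSE]
  k <- length(snps)
  # union-find
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (!is.na(r2[i, j]) && r2[i, j] > threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  sets <- match(roots, unique(roots))
  names(sets) <- snps
  out <- list(sets = sets)
  if (!is.null(models)) {
    out$within_model_correlated <- vapply(seq_len(nrow(models)),
      function(r) {
        sa <- models$snp_a[r]; sb <- models$snp_b[r]
        sa %in% snps && sb %in% snps && sets[sa] == sets[sb]
      }, logical(1))
  }
  out
}

#' Write an LD table as TSV
#' @param ld an `ld_matrix`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ld_tsv <- function(ld, path) {
  k <- length(ld$snp_ids)
  idx <- which(upper.tri(ld$r2), arr.ind = TRUE)
  df <- data.frame(snp1 = ld$snp_ids[idx[, 1]],
                   snp2 = ld$snp_ids[idx[, 2]],
                   r2 = ld$r2[idx],
                   n = ld$n_pairs[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
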