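#' Construct a genotype matrix
#'
#' The central genotype container: additive minor-allele dosages (0, 1, 2,
#' or `NA` for a missing call) for `n` samples at `m` biallelic SNPs, plus
#' per-SNP metadata (chromosome, position, alleles).
#'
#' @param dosage numeric matrix, samples in rows, SNPs in columns; entries
#'   must be 0, 1, 2 or `NA`.
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos`, `ref`,
#'   `alt`; one row per column of `dosage`.
#' @param sample_ids character vector, one per row of `dosage`.
#'
#' @return an object of class `genotype_matrix`: a list with elements
#'   `dosage` (dimnames set to sample and SNP IDs) and `snps`.
#' @export
genotype_matrix <- function(dosage, snps, sample_ids = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("S%04d", seq_len(nrow(dosage)))
  }
  stopifnot(
    nrow(snps) == ncol(dosage),
    length(sample_ids) == nrow(dosage),
    all(c("snp_id", "chrom", "pos") %in% names(snps)),
    anyDuplicated(snps$snp_id) == 0,
    anyDuplicated(sample_ids) == 0
  )
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  if (is.null(snps$ref)) snps$ref <- "A"
  if (is.null(snps$alt)) snps$alt <- "B"
  dimnames(dosage) <- list(sample_ids, snps$snp_id)
  structure(list(dosage = dosage, snps = as.data.frame(snps)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Sample IDs of a genotype matrix
#' @param g a `genotype_matrix`
#' @return character vector of sample identifiers
#' @export
sample_ids <- function(g) rownames(g$dosage)

#' SNP IDs of a genotype matrix
#' @param g a `genotype_matrix`
#' @return character vector of SNP identifiers
#' @export
snp_ids <- function(g) g$snps$snp_id

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param g a `genotype_matrix`
#' @param samples sample IDs (or logical/integer index) to keep
#' @param snps SNP IDs (or logical/integer index) to keep
#' @return the subsetted `genotype_matrix`
#' @export
subset_genotypes <- function(g, samples = NULL, snps = NULL) {
  d <- g$dosage
  meta <- g$snps
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  if (!is.null(snps)) {
    d <- d[, snps, drop = FALSE]
    meta <- meta[match(colnames(d), meta$snp_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  genotype_matrix(d, meta, rownames(d))
}

#' Per-SNP minor allele frequency
#'
#' Allele frequency is the mean non-missing dosage divided by two; MAF is
#' the folded frequency `min(f, 1 - f)`.
#'
#' @param g a `genotype_matrix`
#' @return named numeric vector of MAFs (`NaN` for SNPs with no calls)
#' @export
snp_maf <- function(g) {
  f <- colMeans(g$dosage, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Per-SNP and per-sample call rates
#' @param g a `genotype_matrix`
#' @return named numeric vector of call rates in \[0, 1\]
#' @export
snp_call_rate <- function(g) colMeans(!is.na(g$dosage))

#' @rdname snp_call_rate
#' @export
sample_call_rate <- function(g) rowMeans(!is.na(g$dosage))
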