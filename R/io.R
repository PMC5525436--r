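# Plain-text readers/writers for the formats the pipeline exchanges:
# VCF (GT-only), rectangular dosage TSV, phenotype/covariate TSV,
# BED-like gene annotation TSV and the 3-column knowledge table.

#' Write genotypes as a minimal VCF
#'
#' One record per SNP, a single `GT` FORMAT field, unphased diploid calls
#' (`0/0`, `0/1`, `1/1`, `./.`). ALT is the minor allele, so the dosage
#' equals the ALT-allele count.
#'
#' @param g a `genotype_matrix`
#' @param path output file path (plain text, not gzipped)
#' @return `path`, invisibly
#' @export
write_genotypes_vcf <- function(g, path) {
  gt_codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  d <- g$dosage
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=lipidgwis",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", rownames(d)), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(d)), function(j) {
    calls <- gt_codes[as.character(d[, j])]
    calls[is.na(calls)] <- "./."
    paste(c(g$snps$chrom[j], g$snps$pos[j], g$snps$snp_id[j],
            g$snps$ref[j], g$snps$alt[j], ".", "PASS", ".", "GT", calls),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a GT-only VCF
#'
#' Parses diploid `GT` calls into ALT-allele dosages. Intended for the
#' VCFs this package writes; multi-allelic records are rejected.
#'
#' @param path VCF file path
#' @return a `genotype_matrix`
#' @export
read_genotypes_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  samples <- hdr[-(1:9)]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  snps <- data.frame(
    snp_id = vapply(rows, `[[`, "", 3L),
    chrom = vapply(rows, `[[`, "", 1L),
    pos = as.integer(vapply(rows, `[[`, "", 2L)),
    ref = vapply(rows, `[[`, "", 4L),
    alt = vapply(rows, `[[`, "", 5L)
  )
  if (any(grepl(",", snps$alt, fixed = TRUE))) {
    stop("multi-allelic records are not supported")
  }
  dos <- vapply(rows, function(r) {
    gt <- sub(":.*", "", r[-(1:9)])
    d <- rep(NA_real_, length(gt))
    d[gt %in% c("0/0", "0|0")] <- 0
    d[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
    d[gt %in% c("1/1", "1|1")] <- 2
    d
  }, numeric(length(samples)))
  genotype_matrix(dos, snps, samples)
}

#' Write/read a rectangular dosage table
#'
#' Rows are samples (leading `sample_id` column), columns are SNP IDs.
#' SNP metadata travels in a sidecar `<path>.snps` TSV when written from a
#' `genotype_matrix`, and is reattached on read when present.
#'
#' @param g a `genotype_matrix`
#' @param path output TSV path
#' @return `path` (writer) or a `genotype_matrix` (reader)
#' @export
write_dosage_tsv <- function(g, path) {
  df <- data.frame(sample_id = rownames(g$dosage), g$dosage,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(g$snps, paste0(path, ".snps"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  d <- as.matrix(df[, -1, drop = FALSE])
  rownames(d) <- df$sample_id
  side <- paste0(path, ".snps")
  snps <- if (file.exists(side)) {
    utils::read.delim(side, colClasses = c(chrom = "character"))
  } else {
    data.frame(snp_id = colnames(d), chrom = "NA", pos = seq_len(ncol(d)),
               ref = "A", alt = "B")
  }
  genotype_matrix(d, snps, df$sample_id)
}

#' Write/read a sample-keyed table (phenotypes or covariates) as TSV
#' @param df data.frame with a `sample_id` column
#' @param path TSV path
#' @return `path` (writer) or a data.frame (reader)
#' @export
write_sample_table <- function(df, path) {
  stopifnot("sample_id" %in% names(df))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_table
#' @export
read_sample_table <- function(path) utils::read.delim(path)

#' Read a BED-like gene annotation TSV
#'
#' Expects columns `chrom`, `start`, `end`, `gene` with 0-based half-open
#' coordinates, the convention used throughout this package.
#'
#' @param path TSV path
#' @return data.frame of gene intervals
#' @export
read_gene_annotation <- function(path) {
  ann <- utils::read.delim(path, colClasses = c(chrom = "character"))
  stopifnot(all(c("chrom", "start", "end", "gene") %in% names(ann)))
  validate_gene_annotation(ann)
}

validate_gene_annotation <- function(ann) {
  if (any(ann$start >= ann$end)) stop("gene intervals require start < end")
  if (anyDuplicated(ann$gene)) stop("gene IDs must be unique")
  ann
}

#' Read a knowledge-source gene-pair table
#'
#' Three columns `gene1`, `gene2`, `source`. Gene pairs are unordered;
#' duplicate (pair, source) rows are collapsed.
#'
#' @param path TSV path
#' @return data.frame with canonically ordered, deduplicated rows
#' @export
read_knowledge_base <- function(path) {
  kb <- utils::read.delim(path)
  stopifnot(all(c("gene1", "gene2", "source") %in% names(kb)))
  canonicalize_knowledge_base(kb)
}

canonicalize_knowledge_base <- function(kb) {
  a <- pmin(kb$gene1, kb$gene2)
  b <- pmax(kb$gene1, kb$gene2)
  out <- unique(data.frame(gene1 = a, gene2 = b, source = kb$source,
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
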