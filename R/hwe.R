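#' Hardy-Weinberg exact test
#'
#' Two-sided exact test for a biallelic SNP. Conditioning on the observed
#' allele counts, every heterozygote count with the same parity is
#' possible; the p-value sums the probabilities of all configurations
#' whose probability does not exceed that of the observed one. The
#' distribution is evaluated through the standard ratio recurrence
#' between successive heterozygote counts, which is numerically stable
#' for large samples.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (nonnegative, not all zero).
#' @return exact p-value in (0, 1\].
#' @export
#' @examples
#' hwe_exact_test(100, 0, 0)   # monomorphic: 1
#' hwe_exact_test(30, 40, 30)
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0) || any(is.na(c(n_AA, n_Aa, n_aa)))) {
    stop("genotype counts must be nonnegative")
  }
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all genotype counts are zero")
  rare <- 2 * min(n_AA, n_aa) + n_Aa   # minor allele count
  if (rare == 0) return(1.0)

  # heterozygote counts with the parity of the minor allele count
  h_min <- if (rare > n) 2 * rare - 2 * n else rare %% 2
  hs <- seq.int(h_min, rare, by = 2)

  # unnormalized probabilities via the ratio recurrence, anchored at the
  # distribution mode so extreme tails underflow to zero instead of
  # overflowing
  ratio_up <- function(h) {        # P(h + 2) / P(h)
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    4 * hom_r * hom_c / ((h + 2) * (h + 1))
  }
  mode_h <- rare * (2 * n - rare) / (2 * n)
  mid <- which.min(abs(hs - mode_h))
  probs <- numeric(length(hs))
  probs[mid] <- 1
  if (mid < length(hs)) {
    for (i in mid:(length(hs) - 1)) {
      probs[i + 1] <- probs[i] * ratio_up(hs[i])
    }
  }
  if (mid > 1) {
    for (i in mid:2) {
      probs[i - 1] <- probs[i] / ratio_up(hs[i - 1])
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hs)]
  if (is.na(p_obs)) stop("observed heterozygote count is impossible")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

#' Per-SNP Hardy-Weinberg exact p-values for a genotype matrix
#' @param g a `genotype_matrix`
#' @return named numeric vector of p-values (`NA` for SNPs with no calls)
#' @export
hwe_test_genotypes <- function(g) {
  d <- g$dosage
  vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    n0 <- sum(x == 0, na.rm = TRUE)
    n1 <- sum(x == 1, na.rm = TRUE)
    n2 <- sum(x == 2, na.rm = TRUE)
    if (n0 + n1 + n2 == 0) return(NA_real_)
    hwe_exact_test(n0, n1, n2)
  }, numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(snp_ids(g))
}
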