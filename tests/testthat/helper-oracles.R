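# Independent oracles and small fixture builders shared across tests.

# Direct-enumeration Hardy-Weinberg exact test: log-gamma multinomial
# probability of every heterozygote count consistent with the observed
# allele counts. Independent of the recurrence used by the package.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  rare <- 2 * min(n_AA, n_aa) + n_Aa
  if (rare == 0) return(1.0)
  hs <- seq.int(rare %% 2, rare, by = 2)
  logp <- vapply(hs, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lfactorial(n) - lfactorial(hom_r) - lfactorial(h) -
      lfactorial(hom_c) + h * log(2) +
      lfactorial(rare) + lfactorial(2 * n - rare) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_Aa, hs)]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

# Brute-force connected components by transitive closure of the
# adjacency matrix (reachability), for checking signal_sets.
components_oracle <- function(adj) {
  k <- nrow(adj)
  reach <- adj | diag(TRUE, k)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  match(apply(reach, 1, function(r) paste(which(r), collapse = ",")),
        unique(apply(reach, 1, function(r)
          paste(which(r), collapse = ","))))
}

# Deterministic toy genotype matrix from explicit dosages.
toy_genotypes <- function(dosage, chrom = "1",
                          pos = seq_len(ncol(dosage)) * 1000L) {
  m <- ncol(dosage)
  snps <- data.frame(snp_id = sprintf("t%02d", seq_len(m)),
                     chrom = chrom, pos = pos, ref = "A", alt = "B")
  genotype_matrix(dosage, snps,
                  sprintf("I%03d", seq_len(nrow(dosage))))
}

# Random genotype matrix of independent SNPs at given allele freqs.
random_genotypes <- function(n, mafs, seed) {
  set.seed(seed)
  d <- vapply(mafs, function(p) stats::rbinom(n, 2, p), numeric(n))
  toy_genotypes(d)
}

# Small all-null study configuration used in several calibration tests.
null_config <- function(n = 2000, seed = 1L, noise_sd = 1) {
  sim_config(n_cohorts = 1, n_per_cohort = n, n_snps = 2,
             ld_block_sizes = c(1, 1), within_block_r2 = 0,
             maf_range = c(0.3, 0.4), true_effects = list(),
             noise_sd = noise_sd, missing_rate = 0, seed = seed)
}

# Study with one planted HDL interaction between two independent
# common SNPs; used by recovery and power tests.
planted_config <- function(n = 5000, beta_int = 0.5, seed = 1L,
                           maf = c(0.3, 0.3)) {
  sim_config(n_cohorts = 1, n_per_cohort = n, n_snps = 2,
             ld_block_sizes = c(1, 1), within_block_r2 = 0,
             maf_range = range(maf),
             true_effects = list(true_effect("snp0001", "snp0002",
                                             0.2, 0.2, beta_int,
                                             trait = "HDL")),
             noise_sd = 1, missing_rate = 0, seed = seed)
}

# Multi-cohort configuration with a planted interaction inside LD
# blocks: one merged discovery set and three replication cohorts.
multi_cohort_config <- function(seed, n_discovery = 8000, n_rep = 3000) {
  sim_config(
    n_cohorts = 4, n_per_cohort = c(n_discovery, rep(n_rep, 3)),
    n_snps = 24, ld_block_sizes = rep(4, 6), within_block_r2 = 0.85,
    maf_range = c(0.3, 0.5),
    true_effects = list(true_effect("snp0002", "snp0010", 0.15, 0.15,
                                    0.5, trait = "HDL")),
    noise_sd = 1, n_discovery_cohorts = 1, seed = seed)
}
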