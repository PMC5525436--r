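# Multi-cohort synthetic data generator. Genotypes use a latent-Gaussian
# threshold model: per haplotype, a block-wise AR(1) latent vector is
# thresholded at the per-SNP allele-frequency quantile and the two
# haplotypes are summed, giving valid {0,1,2} dosages with a tunable
# within-block dosage r2.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic multi-cohort study: cohort layout,
#' LD-block structure, allele frequencies, planted genetic effects,
#' covariate effects and residual noise.
#'
#' @param n_cohorts number of cohorts (>= 1).
#' @param n_per_cohort samples per cohort; scalar or vector of length
#'   `n_cohorts`.
#' @param n_snps total number of SNPs; must equal `sum(ld_block_sizes)`.
#' @param ld_block_sizes integer vector of block sizes. SNPs in different
#'   blocks are generated independently.
#' @param within_block_r2 target squared correlation between adjacent SNPs
#'   within a block, in \[0, 1).
#' @param maf_range minor-allele-frequency interval within \[0.05, 0.5\].
#' @param true_effects list of [true_effect()] objects (planted main and
#'   interaction effects).
#' @param covariate_effects named numeric vector of covariate coefficients
#'   applied to every trait's linear scale (log scale for TG).
#' @param noise_sd residual SD per trait: scalar, or named vector with
#'   names among `HDL`, `LDL`, `TG`, `TC`. The TG value is the SD of
#'   log(TG). The TC value is measurement noise added on top of the
#'   Friedewald identity TC = LDL + HDL + 0.45 TG; set it to 0 for an
#'   exact round trip.
#' @param missing_rate genotype missingness, injected completely at
#'   random (default 1%).
#' @param n_discovery_cohorts how many leading cohorts form the merged
#'   discovery set; the rest are independent replication cohorts.
#' @param seed integer seed; identical config + seed reproduces identical
#'   output.
#'
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cohorts = 1,
                       n_per_cohort = 1000,
                       n_snps = 20,
                       ld_block_sizes = rep(5, 4),
                       within_block_r2 = 0.6,
                       maf_range = c(0.05, 0.5),
                       true_effects = list(),
                       covariate_effects = c(age = 0.003, sex = -0.08,
                                             bmi = 0.004),
                       noise_sd = c(HDL = 0.35, LDL = 0.9,
                                    TG = 0.45, TC = 0.1),
                       missing_rate = 0.01,
                       n_discovery_cohorts = 1,
                       seed = 1L) {
  if (length(n_per_cohort) == 1) {
    n_per_cohort <- rep(n_per_cohort, n_cohorts)
  }
  if (sum(ld_block_sizes) != n_snps) {
    stop("sum(ld_block_sizes) must equal n_snps")
  }
  if (within_block_r2 < 0 || within_block_r2 >= 1) {
    stop("within_block_r2 must lie in [0, 1)")
  }
  if (maf_range[1] < 0.05 - 1e-12 || maf_range[2] > 0.5 + 1e-12 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be an interval within [0.05, 0.5]")
  }
  if (length(n_per_cohort) != n_cohorts || any(n_per_cohort < 1)) {
    stop("n_per_cohort must give a positive size for each cohort")
  }
  if (n_discovery_cohorts < 1 || n_discovery_cohorts > n_cohorts) {
    stop("n_discovery_cohorts must be in 1..n_cohorts")
  }
  nsd <- c(HDL = NA_real_, LDL = NA_real_, TG = NA_real_, TC = NA_real_)
  if (is.null(names(noise_sd))) {
    nsd[] <- rep_len(noise_sd, 4)
  } else {
    nsd[names(noise_sd)] <- noise_sd
    nsd[is.na(nsd)] <- 0
  }
  if (any(nsd[c("HDL", "LDL", "TG")] <= 0)) {
    stop("noise_sd must be positive for HDL, LDL and TG")
  }
  for (eff in true_effects) stopifnot(inherits(eff, "true_effect"))
  structure(list(
    n_cohorts = as.integer(n_cohorts),
    n_per_cohort = as.integer(n_per_cohort),
    n_snps = as.integer(n_snps),
    ld_block_sizes = as.integer(ld_block_sizes),
    within_block_r2 = within_block_r2,
    maf_range = maf_range,
    true_effects = true_effects,
    covariate_effects = covariate_effects,
    noise_sd = nsd,
    missing_rate = missing_rate,
    n_discovery_cohorts = as.integer(n_discovery_cohorts),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Planted genetic effect
#'
#' Describes one generative truth: main-effect coefficients for one or two
#' SNPs and, optionally, a multiplicative dosage-product interaction
#' coefficient, all on one trait's linear scale.
#'
#' @param snp_a,snp_b SNP IDs; `snp_b` is required when
#'   `beta_interaction != 0`.
#' @param beta_main_a,beta_main_b main-effect coefficients per dosage unit.
#' @param beta_interaction coefficient of the dosage product
#'   `g_a * g_b`.
#' @param trait one of `"HDL"`, `"LDL"`, `"TC"`, `"TG"` (TG effects act on
#'   the log scale).
#' @return a `true_effect` object.
#' @export
true_effect <- function(snp_a, snp_b = NA_character_, beta_main_a = 0,
                        beta_main_b = 0, beta_interaction = 0,
                        trait = "HDL") {
  trait <- match.arg(trait, c("HDL", "LDL", "TC", "TG"))
  if (beta_interaction != 0 && is.na(snp_b)) {
    stop("snp_b is required when beta_interaction != 0")
  }
  structure(list(snp_a = snp_a, snp_b = snp_b, beta_main_a = beta_main_a,
                 beta_main_b = beta_main_b,
                 beta_interaction = beta_interaction, trait = trait),
            class = "true_effect")
}

# P(Z1 < t1, Z2 < t2) for standard bivariate normal with correlation rho,
# by univariate quadrature (no bivariate-normal dependency needed).
bvn_lower <- function(t1, t2, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(t1) * stats::pnorm(t2))
  f <- function(z) {
    stats::dnorm(z) * stats::pnorm((t2 - rho * z) / sqrt(1 - rho^2))
  }
  stats::integrate(f, -8, t1, rel.tol = 1e-9)$value
}

# Latent correlation giving binary (allele-indicator) correlation r_b for
# allele frequencies p1, p2. Capped when r_b is infeasible for the pair.
calibrate_latent_rho <- function(p1, p2, r_b) {
  if (r_b <= 0) return(0)
  t1 <- stats::qnorm(p1); t2 <- stats::qnorm(p2)
  target <- p1 * p2 + r_b * sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  upper <- min(p1, p2)  # Frechet bound on P11
  if (target >= upper - 1e-10) return(0.9999)
  g <- function(rho) bvn_lower(t1, t2, rho) - target
  stats::uniroot(g, c(0, 0.9999), tol = 1e-8)$root
}

#' Simulate LD-block structured genotypes
#'
#' Generates biallelic dosages for all cohorts in one matrix. Within each
#' block, a per-haplotype latent AR(1) Gaussian is thresholded at the
#' allele-frequency quantile; the latent correlation of each adjacent pair
#' is calibrated so that the dosage r-squared of adjacent SNPs
#' approximates `within_block_r2`. Blocks are independent. Missing calls
#' are injected completely at random at `config$missing_rate`.
#'
#' Under strong target LD, per-SNP allele frequencies are drawn with
#' within-block shrinkage toward a common block frequency (high r2 is
#' mathematically impossible between SNPs with very different MAFs).
#'
#' @param config a [sim_config()].
#' @return a `genotype_matrix` with `sum(n_per_cohort)` samples.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- sum(config$n_per_cohort)
  m <- config$n_snps
  blocks <- config$ld_block_sizes
  r_b <- sqrt(config$within_block_r2)
  w <- r_b  # MAF shrinkage weight grows with target LD

  # per-SNP MAF: mixture of a block-level and a SNP-level uniform draw
  maf <- numeric(m)
  block_id <- rep(seq_along(blocks), blocks)
  for (b in seq_along(blocks)) {
    idx <- which(block_id == b)
    u <- w * stats::runif(1) + (1 - w) * stats::runif(length(idx))
    maf[idx] <- config$maf_range[1] + u * diff(config$maf_range)
  }

  dosage <- matrix(0, n, m)
  for (b in seq_along(blocks)) {
    idx <- which(block_id == b)
    k <- length(idx)
    rho <- if (k > 1) {
      vapply(seq_len(k - 1), function(j) {
        calibrate_latent_rho(maf[idx[j]], maf[idx[j + 1]], r_b)
      }, numeric(1))
    } else numeric(0)
    for (hap in 1:2) {
      z <- matrix(stats::rnorm(n * k), n, k)
      if (k > 1) {
        for (j in 2:k) {
          z[, j] <- rho[j - 1] * z[, j - 1] +
            sqrt(1 - rho[j - 1]^2) * z[, j]
        }
      }
      alleles <- sweep(z, 2, stats::qnorm(maf[idx]), `<`)
      dosage[, idx] <- dosage[, idx] + alleles
    }
  }
  if (config$missing_rate > 0) {
    miss <- stats::runif(n * m) < config$missing_rate
    dosage[matrix(miss, n, m)] <- NA
  }

  pos <- integer(m)
  for (b in seq_along(blocks)) {
    idx <- which(block_id == b)
    pos[idx] <- (b - 1L) * 1000000L + 10001L + (seq_along(idx) - 1L) * 2000L
  }
  snps <- data.frame(
    snp_id = sprintf("snp%04d", seq_len(m)),
    chrom = "1",
    pos = pos,
    ref = "A",
    alt = "B",
    block = block_id
  )
  genotype_matrix(dosage, snps, sprintf("S%05d", seq_len(n)))
}

#' Simulate the covariate table
#'
#' Emulates the covariates adjusted for in lipid interaction models: age
#' (uniform 21-80 years, adults only), sex, current smoking, type 2
#' diabetes and lipid-lowering medication (Bernoulli), BMI (Gaussian,
#' mean 27, SD 4.5 kg/m2), and ten synthetic principal components
#' (independent standard Gaussians; see [compute_pcs()] for PCs derived
#' from the genotypes themselves).
#'
#' @param n number of samples (> 0).
#' @param seed integer seed.
#' @param sample_ids optional sample IDs (default `S00001`...).
#' @return data.frame with `sample_id` plus 16 covariate columns.
#' @export
simulate_covariates <- function(n, seed = 1L, sample_ids = NULL) {
  if (n <= 0) stop("n must be positive")
  set.seed(seed)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%05d", seq_len(n))
  X <- data.frame(
    sample_id = sample_ids,
    age = stats::runif(n, 21, 80),
    sex = stats::rbinom(n, 1, 0.5),
    bmi = stats::rnorm(n, 27, 4.5),
    smoking = stats::rbinom(n, 1, 0.25),
    t2d = stats::rbinom(n, 1, 0.10),
    lipid_med = stats::rbinom(n, 1, 0.15)
  )
  pcs <- matrix(stats::rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("PC", 1:10)))
  cbind(X, as.data.frame(pcs))
}

#' Default covariate column names used in the regression models
#' @return character vector of the 16 covariate column names
#' @export
default_covariates <- function() {
  c("age", "bmi", "lipid_med", "t2d", "smoking", "sex", paste0("PC", 1:10))
}

#' Simulate the lipid panel
#'
#' Builds each trait as intercept + planted genetic effects + covariate
#' effects + Gaussian noise. TG is generated as `exp(linear predictor +
#' noise)` so that log(TG) is the linear-model scale. TC is built from the
#' Friedewald identity `TC = LDL + HDL + 0.45 TG` plus TC-level noise (and
#' any TC-targeted genetic effects), so derived LDL round-trips when the
#' TC noise SD is zero. Intercepts give physiologic means (HDL 1.4,
#' LDL 3.0, TG 1.5 mmol/L).
#'
#' @param G a `genotype_matrix` (missing dosages are mean-imputed for the
#'   generative linear predictor only).
#' @param X covariate table aligned with `G` by `sample_id`.
#' @param config a [sim_config()]; uses `true_effects`,
#'   `covariate_effects`, `noise_sd` and `seed`.
#' @return data.frame: `sample_id`, `tc`, `hdl`, `ldl`, `tg` (mmol/L).
#' @export
simulate_phenotypes <- function(G, X, config) {
  stopifnot(identical(sample_ids(G), X$sample_id))
  set.seed(config$seed + 2L)
  n <- nrow(X)
  d <- G$dosage
  cm <- colMeans(d, na.rm = TRUE)
  for (j in seq_len(ncol(d))) d[is.na(d[, j]), j] <- cm[j]

  lp <- matrix(0, n, 4, dimnames = list(NULL, c("HDL", "LDL", "TC", "TG")))
  for (eff in config$true_effects) {
    if (!eff$snp_a %in% colnames(d)) {
      stop("true effect references SNP absent from G: ", eff$snp_a)
    }
    ga <- d[, eff$snp_a]
    contrib <- eff$beta_main_a * ga
    if (!is.na(eff$snp_b)) {
      if (!eff$snp_b %in% colnames(d)) {
        stop("true effect references SNP absent from G: ", eff$snp_b)
      }
      gb <- d[, eff$snp_b]
      contrib <- contrib + eff$beta_main_b * gb +
        eff$beta_interaction * ga * gb
    }
    lp[, eff$trait] <- lp[, eff$trait] + contrib
  }
  cov_lp <- rep(0, n)
  for (nm in names(config$covariate_effects)) {
    cov_lp <- cov_lp + config$covariate_effects[[nm]] * X[[nm]]
  }
  sd <- config$noise_sd
  hdl <- 1.4 + lp[, "HDL"] + cov_lp + stats::rnorm(n, 0, sd[["HDL"]])
  ldl <- 3.0 + lp[, "LDL"] + cov_lp + stats::rnorm(n, 0, sd[["LDL"]])
  tg <- exp(log(1.5) + lp[, "TG"] + cov_lp + stats::rnorm(n, 0, sd[["TG"]]))
  tc <- ldl + hdl + 0.45 * tg + lp[, "TC"] +
    (if (sd[["TC"]] > 0) stats::rnorm(n, 0, sd[["TC"]]) else 0)
  data.frame(sample_id = X$sample_id, tc = tc, hdl = hdl, ldl = ldl,
             tg = tg)
}

#' One gene per LD block
#'
#' Convenience annotation for simulated data: each LD block becomes one
#' gene whose interval spans the block's SNP positions (0-based
#' half-open).
#'
#' @param G a simulated `genotype_matrix` (needs the `block` column).
#' @return data.frame `gene`, `chrom`, `start`, `end`.
#' @export
simulate_gene_annotation <- function(G) {
  stopifnot("block" %in% names(G$snps))
  sp <- split(G$snps, G$snps$block)
  out <- do.call(rbind, lapply(sp, function(s) {
    data.frame(gene = sprintf("GENE%02d", s$block[1]), chrom = s$chrom[1],
               start = min(s$pos) - 1L, end = max(s$pos) + 1L)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a knowledge-source gene-pair table
#'
#' Each unordered gene pair is supported by `Binomial(n_sources, density)`
#' distinct sources, emulating curated interaction databases (pathway and
#' ontology resources). With `density = 1` every pair is supported by all
#' sources; with `density = 0` the table is empty.
#'
#' @param genes gene annotation data.frame (>= 2 genes).
#' @param n_sources number of distinct knowledge sources (>= 1).
#' @param density per-source support probability in \[0, 1\].
#' @param seed integer seed.
#' @return data.frame `gene1`, `gene2`, `source`.
#' @export
simulate_knowledge_base <- function(genes, n_sources = 6, density = 0.5,
                                    seed = 1L) {
  if (n_sources < 1) stop("n_sources must be >= 1")
  if (nrow(genes) < 2) stop("need at least 2 genes")
  set.seed(seed)
  ids <- sort(genes$gene)
  pairs <- utils::combn(ids, 2)
  src_names <- sprintf("source%02d", seq_len(n_sources))
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    hit <- stats::runif(n_sources) < density
    if (!any(hit)) return(NULL)
    data.frame(gene1 = pairs[1, i], gene2 = pairs[2, i],
               source = src_names[hit])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(gene1 = character(), gene2 = character(),
                      source = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Partition a simulated study into cohorts
#'
#' Splits samples into disjoint cohorts in ID order: the first
#' `config$n_discovery_cohorts` cohorts are flagged for merging into the
#' discovery set, the remainder are independent replication cohorts.
#'
#' @param G,X,P genotype matrix, covariate table, lipid panel (aligned).
#' @param config a [sim_config()].
#' @return list of cohort datasets, each a list with `name`, `role`
#'   (`"discovery"` / `"replication"`), `genotypes`, `covariates`,
#'   `phenotypes`.
#' @export
split_cohorts <- function(G, X, P, config) {
  sizes <- config$n_per_cohort
  if (config$n_cohorts < 2) stop("n_cohorts must be >= 2 to split")
  if (sum(sizes) > nrow(G$dosage)) {
    stop("cohort partition exceeds the number of samples")
  }
  offsets <- c(0L, cumsum(sizes))
  lapply(seq_len(config$n_cohorts), function(i) {
    rows <- (offsets[i] + 1L):offsets[i + 1L]
    ids <- sample_ids(G)[rows]
    list(
      name = sprintf("cohort%02d", i),
      role = if (i <= config$n_discovery_cohorts) "discovery"
             else "replication",
      genotypes = subset_genotypes(G, samples = ids),
      covariates = X[match(ids, X$sample_id), , drop = FALSE],
      phenotypes = P[match(ids, P$sample_id), , drop = FALSE]
    )
  })
}

#' Merge several cohorts into one dataset
#' @param cohorts list of cohort datasets (as from [split_cohorts()])
#' @param name name for the merged dataset
#' @return a single cohort dataset
#' @export
merge_cohorts <- function(cohorts, name = "discovery") {
  d <- do.call(rbind, lapply(cohorts, function(co) co$genotypes$dosage))
  g <- genotype_matrix(d, cohorts[[1]]$genotypes$snps, rownames(d))
  X <- do.call(rbind, lapply(cohorts, function(co) co$covariates))
  P <- do.call(rbind, lapply(cohorts, function(co) co$phenotypes))
  rownames(X) <- rownames(P) <- NULL
  list(name = name, role = "discovery", genotypes = g, covariates = X,
       phenotypes = P)
}

#' Simulate a complete multi-cohort study
#'
#' Orchestrates [simulate_genotypes()], [simulate_covariates()],
#' [simulate_phenotypes()] and [split_cohorts()] under one seed.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes`, `covariates`, `phenotypes`, `cohorts`,
#'   `config`.
#' @export
simulate_study <- function(config) {
  G <- simulate_genotypes(config)
  X <- simulate_covariates(sum(config$n_per_cohort),
                           seed = config$seed + 1L,
                           sample_ids = sample_ids(G))
  P <- simulate_phenotypes(G, X, config)
  cohorts <- if (config$n_cohorts >= 2) split_cohorts(G, X, P, config)
             else list(list(name = "cohort01", role = "discovery",
                            genotypes = G, covariates = X,
                            phenotypes = P))
  list(genotypes = G, covariates = X, phenotypes = P, cohorts = cohorts,
       config = config)
}
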