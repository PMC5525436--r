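---
title: "Methods: SNP-SNP interaction discovery and replication for lipid traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP-SNP interaction discovery and replication for lipid traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidgwis)
```

## The statistical model

`lipidgwis` tests for pairwise epistasis on quantitative lipid traits
(HDL-C, LDL-C, total cholesterol, and log-transformed triglycerides)
with nested linear models. For a candidate SNP pair the reduced model is

    y = a + b1*SNP1 + b2*SNP2 + b3*age + b4*BMI + b5*medication +
        b6*T2D + b7*smoking + b8*sex + b9..b18*PC1..PC10

and the full model adds the single multiplicative term
`b19*(SNP1*SNP2)`, where SNP terms are additive minor-allele dosages in
{0, 1, 2}. Both models are fit by OLS on the identical complete-case
sample, and the interaction is judged by the likelihood ratio statistic

    LRT = n * log(RSS_reduced / RSS_full) = 2 * (ll_full - ll_reduced),

referred to a chi-square distribution with one degree of freedom. The
chi-square reference (rather than the partial F) matches the test's
name; the F-test agrees to within a fraction of a percent at the sample
sizes involved, and that agreement is checked in the test suite rather
than assumed. The additive dosage coding is the convention of the
marginal GWAS work this design builds on; the dosage-product term is
the standard multiplicative-interaction parameterization.

Per model we also report `diff_r2 = r2_full - r2_reduced`, the variance
share attributable to the interaction term, which is nonnegative by
nesting (asserted up to numerical slack).

### Degenerate fits

Rank-deficient designs (e.g. an interaction column collinear with the
main effects) return `status = "collinear"`; complete-case counts at or
below the parameter count return `"insufficient_n"`; SNPs constant on
the analysis sample return `"monomorphic"`. An exact fit (RSS = 0) is
flagged and its log-likelihood guarded at `+Inf`, with the LRT defined
as 0 when both models fit exactly. Batch runs never abort on a failing
model; failures travel as per-row statuses.

## Two candidate-model arms

**Main-effect filter (MEF).** SNPs are LD-pruned (greedy scan in
genomic-position order, removing any SNP with r² > 0.6 against an
already-retained SNP; higher-MAF member kept on position ties), then
screened by the marginal model `y ~ SNP + covariates`. SNPs with
marginal p < 0.001 are paired exhaustively: m passing SNPs give
C(m, 2) models. The p < 0.001 screen deliberately admits loci without
genome-wide-significant main effects while keeping the pair count
manageable.

**Knowledge arm.** Gene pairs supported by at least five distinct
curated knowledge sources define the candidate space. SNPs map to a
gene when they fall within 50 kb of it; with 0-based half-open gene
intervals the window test is `start - 50000 <= pos < end + 50000`, so a
SNP exactly 50,000 bp upstream is included and one at 50,001 bp is not.
Each qualifying gene pair contributes all cross-gene SNP pairs; SNPs
mapping to both genes of a pair are excluded, duplicate pairs arising
from different gene pairs are deduplicated by canonical key, and no LD
pruning is applied (the models are cross-gene by construction). Source
support is counted as distinct source names, not table rows; a
weighted source score would be a straightforward extension but plain
counting is what is implemented.

## Replication design

Models reaching LRT p < 0.001 in the discovery set (strict inequality;
a Bonferroni-adjusted discovery threshold is available as an option)
are ranked by p-value and carried to replication. For each original
model, proxy models are built from SNPs with r² > 0.8 with either
member — here found in the discovery genotypes themselves, since the
package has no external reference-panel lookup; with real data one
would normally draw proxies from a reference panel, and this
within-data substitute is the documented divergence.

The replication significance threshold is Bonferroni-like:
`alpha / (n_original_models * n_cohorts)`, counting only original
(non-proxy) models. Display values round to one significant figure
(0.05/1560 prints as 0.00003) while comparisons use the unrounded
value. An original model plus its proxies form one LD *signal*: a
cohort replicates the signal when any member passes the threshold
there, and it counts once per cohort no matter how many members pass.
The lead (lowest-p) member per cohort is reported, with direction
concordance defined as the sign of its interaction beta matching the
discovery sign. Models whose SNPs a cohort does not carry are recorded
as `snp_absent`, mirroring what happens when proxy SNPs are missing
from a genotyping array.

## Phenotype preparation

All lipid values are analyzed in mmol/L (mg/dL inputs divide by 38.67
for cholesterol and 88.57 for triglycerides — the standard clinical
factors). When no measured LDL is supplied it is derived by
Friedewald's formula `LDL = TC - HDL - k*TG` (k = 0.45 in mmol/L, 0.20
in mg/dL), set missing whenever TG exceeds 4.51 mmol/L (400 mg/dL)
where the formula is invalid; the cutoff rule applies only to derived
LDL, never to supplied measurements. TG is log-transformed (natural
log; the base only rescales coefficients, not LRT p-values) and all TG
analyses run on `log_tg`.

## Genotype quality control

The canonical order, logged in the QC report, is: SNP call rate
(retain >= 0.95) -> Hardy-Weinberg exact test (remove p < 1e-7) ->
sample call rate (retain >= 0.90) -> relatedness (remove one member of
each pair with pi-hat > 0.3) -> MAF (retain >= 0.05, computed last,
i.e. after relatedness removal, as a per-analysis filter). All
thresholds are configurable. The report stores the surviving ID lists,
so `apply_qc_report()` reproduces the filtered matrix bit-exactly.

The HWE test is the exact two-sided test conditioning on allele
counts: the p-value sums the probabilities of all heterozygote counts
whose probability does not exceed the observed one. It is evaluated by
the ratio recurrence between successive heterozygote counts anchored
at the distribution mode, which is stable for tens of thousands of
samples; the test suite sweeps every genotype configuration with
n <= 50 against a direct log-gamma enumeration oracle (agreement to
1e-12).

Relatedness uses the method-of-moments IBD estimator: observed IBS
state counts are compared with their expectations under IBD 0/1/2
given sample allele frequencies, solved sequentially for the IBD-state
probabilities, with `pihat = P(IBD=1)/2 + P(IBD=2)` clamped to [0, 1]
(the raw value is kept for diagnostics). Removal is greedy by
over-threshold pair count with deterministic tie-breaks (lower call
rate, then lexicographic ID) — near-minimal and reproducible.

Principal components are computed from mean-imputed, per-SNP
standardized dosages via SVD, with the deterministic sign convention
that each component's largest-magnitude loading is positive. Mean
imputation is used for PCA only; all regression stages are
complete-case per model.

## The synthetic multi-cohort generator

Real consortium cohort data are access-controlled, so the package
ships a generator that reproduces the *statistical structure* the
analysis assumes, making every stage testable at desk scale.

**Genotypes.** Within each LD block, one latent AR(1) Gaussian vector
per haplotype is thresholded at the per-SNP allele-frequency quantile
and the two haplotypes are summed — always-valid {0,1,2} dosages with
Hardy-Weinberg-consistent genotype frequencies. The latent correlation
of each adjacent pair is calibrated numerically (bivariate-normal
orthant probability solved by quadrature and root-finding) so that the
*dosage* r² of adjacent SNPs matches the requested `within_block_r2`;
at a target of 0.9 and n = 5000 the realized adjacent r² lands within
a few hundredths of target. Because high r² is impossible between SNPs
of very different allele frequencies (the Frechet bound), per-SNP MAFs
are drawn with within-block shrinkage toward a common block frequency
that grows with the LD target — which is also how allele frequencies
behave in real high-LD blocks. Blocks are independent; missing calls
are injected completely at random (default 1%).

**Phenotypes.** Each trait is intercept + planted genetic effects +
covariate effects + Gaussian noise. TG is generated as
`exp(linear predictor + noise)` so that log(TG) is the linear-model
scale, and TC is built from the Friedewald identity
`TC = LDL + HDL + 0.45*TG` plus optional TC-level measurement noise —
with that noise at zero, Friedewald derivation round-trips the
generated LDL exactly, which the tests exploit. Intercepts give
physiologic means (HDL 1.4, LDL 3.0, TG 1.5 mmol/L); they are
presentation choices with no inferential role. At large noise SDs the
Gaussian traits can go nonphysiologically low; no clamping is applied,
because truncation would distort the calibration properties the tests
rely on. Residual SDs and effect sizes are free parameters of the
simulation, not estimates of any real cohort.

**Covariates.** Age uniform on 21-80 years (adults only), sex,
smoking, T2D and lipid-medication indicators with realistic
prevalences, Gaussian BMI, and ten synthetic PCs drawn as independent
standard Gaussians — a single simulated population has no ancestry
structure for real PCs to capture; `compute_pcs()` supplies real ones
when wanted.

**What passing tests do and do not show.** The generator emulates LD
blocks, planted multiplicative interactions and covariate structure;
it does not emulate family structure, ancestry admixture, imputation
dosages, genotyping batch effects, or trait distributions beyond
(log-)normal. Calibration and recovery results on synthetic data
therefore validate the machinery, not the biology of any particular
cohort.

## Problem sizes and numerical choices

The shipped checks use: null calibration with 1000 replicates at
n = 2000 (type-I error at alpha = 0.05 expected in [0.035, 0.065];
Kolmogorov-Smirnov uniformity at the 1% level); recovery of a planted
interaction coefficient of 0.5 at n = 5000 over 100 replicates (within
3 SE in at least 95%); and an end-to-end scenario — discovery n = 8000
merged, three replication cohorts of n = 3000, 24 SNPs in six LD
blocks at r² 0.85, planted interaction beta 0.5 between two blocks —
over 20 seeded runs, requiring selection and >= 2-cohort replication
of the planted signal in at least 90%. These sizes keep each property
estimable with comfortable Monte-Carlo margins while remaining
desk-scale. In the end-to-end scenario the pairwise pi-hat scan is
omitted from QC: the simulated samples are unrelated by construction
and the O(n²m) pair scan adds nothing; relatedness removal is
exercised separately on small fixtures.

Other numerical choices: LRT computed from the RSS ratio (identical to
2*delta-log-likelihood to 1e-8, asserted); strict inequalities at the
selection (p < 0.001), pruning (r² > 0.6 removed), proxy (r² > 0.8)
and signal (r² > 0.1) thresholds, with the boundary conventions of
each operation unit-tested; greedy deterministic tie-breaks wherever
an arbitrary choice is needed, so identical inputs give byte-identical
outputs.

## Known limitations

- Proxies come from the analysis data, not an external reference
  panel; in small cohorts their r² estimates are noisy.
- The knowledge arm consumes a pre-digested three-column gene-pair
  table; it does not reimplement any knowledge-database loader or
  source weighting.
- Binary traits, robust/sandwich errors and mixed models for residual
  relatedness are out of scope; relatedness is handled by removal.
- Global (not windowed) LD pruning: fine at candidate-gene scale,
  quadratic in SNP count if pushed to genome scale.
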