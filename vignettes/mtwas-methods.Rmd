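---
title: "Methods: multi-tissue expression and splicing TWAS from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-tissue expression and splicing TWAS from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`mtwas` implements a summary-statistic transcriptome-wide association
(TWAS) pipeline for case-control traits, of the kind used to dissect
estrogen-receptor-defined breast cancer subtypes: per-tissue association of
genetically predicted gene expression and intron excision with the trait,
aggregation across introns and tissues with the aggregated Cauchy
association test (ACAT), conditional analysis against known GWAS index
variants in both directions (including a proportion-mediated summary), and
gene-level probabilistic fine-mapping. All stages consume only GWAS summary
statistics, SNP-weight prediction models, and an LD reference panel.

This vignette is the package's account of the statistical model behind each
stage, the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
that were genuinely open.

# The model, stage by stage

## Harmonization and meta-analysis

All z-scores are oriented to the LD panel's effect allele ("effect allele
adds weight"); harmonization flips GWAS z-scores and never model weights,
so there is a single source of orientation truth. Strand-ambiguous
palindromic SNPs (A/T, C/G) are dropped rather than frequency-resolved — a
conservative choice, since allele frequencies are not part of the input
contract. Two studies are combined per variant by inverse-variance
fixed-effects weighting,
$\hat\beta = (\sum_i \beta_i/\mathrm{SE}_i^2)/(\sum_i 1/\mathrm{SE}_i^2)$,
$\mathrm{SE} = (\sum_i 1/\mathrm{SE}_i^2)^{-1/2}$; effect-size weighting is
an assumption (sample-size weighting is the main alternative in standard
meta-analysis tools), and p-values are always recomputed from z as the
two-sided normal tail for cross-stage consistency.

## Z-score imputation

Model SNPs absent from the GWAS are imputed by the Gaussian
conditional-mean rule: with marginal z-scores in a region distributed
approximately $N(\mathbf{0}, R)$ under the null, where $R$ is the LD
correlation matrix,

$$\hat z_t = R_{to}\,(R_{oo} + \lambda I)^{-1} z_o,\qquad
r^2_{pred} = \mathrm{diag}\!\left(R_{to}(R_{oo}+\lambda I)^{-1}R_{ot}\right).$$

Defaults $\lambda = 0.1$ and an $r^2_{pred}$ floor of $0.6$ are the
conventional operating points for this estimator; both are exposed as
arguments because the underlying model does not fix them. Imputation never
crosses region boundaries, and low-quality imputations are flagged and
withheld from the TWAS rather than silently used.

## The per-tissue TWAS statistic

For a feature (gene expression or intron excision ratio) with model weights
$w_l$ over SNPs $l$, the summary-based association z-score is

$$z_g = \sum_l w_l \frac{\sigma_l}{\sigma_g} z_l, \qquad
\sigma_g^2 = w^\top \Gamma w,$$

with $\sigma_l$ and $\Gamma$ the SNP dosage SDs and covariance from the LD
reference (not GWAS allele frequencies — the reference panel is the single
variance source). Model SNPs without a usable z are dropped and $\sigma_g$
recomputed over the SNPs used, matching the drop-and-renormalize behavior
of the standard implementations; coverage is reported and results under
50% coverage are flagged. The statistic is invariant to rescaling all
weights and equivariant under sign flips, and under the null is standard
normal — both properties are exercised by the test suite at scale.

## Two-step ACAT aggregation

Component p-values are combined by the Cauchy statistic
$T = \sum_k w_k \tan\{(0.5 - p_k)\pi\}$ with combined p-value
$0.5 - \arctan(T)/\pi$, which is robust to dependence among components.
The splicing analysis aggregates twice: intron-level p-values are combined
into a per-tissue gene p-value, then gene-level p-values are combined
across tissues. Tissues are weighted equally ($1/11$ with the full roster;
for genes modeled in fewer tissues the weights remain equal over the
tissues that have models). Untestable tissues (no usable SNPs or
$\sigma_g^2 \le 0$) are treated as absent — they do not enter $K$ — which
is one of the places the upstream description is silent. A
$\sqrt{n}$-weighted variant is available behind `weight_mode = "sqrt_n"`
for sensitivity analyses; equal weighting is the default and the primary
analysis.

Numerically, $p_k < 10^{-15}$ contributes its asymptotic term
$w_k/(p_k\pi)$ (avoiding `tan` overflow), very large $T$ maps to
$1/(\pi T)$, and $p_k = 1$ is clipped to $1 - 10^{-16}$ with a warning.
These branches keep the combination exact to machine precision down to
component p-values of $10^{-300}$.

Each approach (expression; splicing) has its own Bonferroni universe — the
number of genes testable by that approach — and a gene is "identified"
when it passes either gate. Thresholds are displayed at two significant
figures (0.05 over 19,288 genes prints as 2.6e-06) while comparisons use
the exact value.

## Conditional analysis and mediation

Forward direction: model-SNP z-scores are residualized on all genome-wide
significant index variants within ±2 Mb of the feature's span,

$$z^{adj}_j = \frac{z_j - R_{jI}R_{II}^{-1} z_I}
{\sqrt{1 - R_{jI}R_{II}^{-1}R_{Ij}}},$$

and the TWAS and ACAT stages are re-run unchanged (weights are never
modified). Index sets are LD-pruned at $r^2 > 0.9$ and $R_{II}$ receives a
$10^{-6}$ ridge; conditional variances at or below $10^{-4}$ take a
collinearity path ($z^{adj} = 0$, flagged). A remark on invariance: the
standardized formula above is not literally idempotent — re-applying it to
an already-conditioned vector rescales by the conditional SD again, because
the LD matrix is not simultaneously updated to conditional correlations.
The residualization (numerator) map is the projection, and that is the
invariant the test suite asserts.

Reverse direction: each index variant's z-score is conditioned on the
eQTL/sQTL used by the locus's prediction models, jointly across genes at
the locus (a per-gene mode is available via `per_gene`). The adjusted
(direct) log odds-ratio is reconstructed as
$\beta_{direct} = z^{adj}\cdot \mathrm{SE}_{total}$ — i.e. the SE is
treated as unchanged by conditioning, a standardized-genotype
approximation that is the one point where an OR-scale contract must be
imposed on z-scale algebra; it is isolated in a single function. With
$\mathrm{OR}_{indirect} = \mathrm{OR}_{total}/\mathrm{OR}_{direct}$, the
proportion mediated is

$$\mathrm{PM} = \frac{\mathrm{OR}_{direct}\,(\mathrm{OR}_{indirect}-1)}
{\mathrm{OR}_{total}-1},$$

the only definition under which PM is exactly 1 when the direct effect is
null and exactly 0 when adjustment changes nothing. A variant is classified
mediated when $\mathrm{PM} > 0.5$ and its adjusted p-value exceeds
$5\times 10^{-8}$. If an index variant is itself a model SNP, conditioning
on itself takes the collinearity path and yields full mediation — the
expected behavior when the GWAS signal *is* the eQTL.

## Gene-level fine-mapping

Within a region and tissue, the genetic correlation among predicted
features induced jointly by LD and model weights is
$\Omega_{ij} = w_i^\top \Gamma w_j / (\sigma_i\sigma_j)$. Causal
configurations $C$ with $|C| \le k$ (including the empty set) are
enumerated; under $C$ the feature z-scores are modeled as
$z \sim N(\mathbf{0},\ \Omega + v\,\Omega_{\cdot C}\Omega_{C\cdot})$ with
prior $\pi_0^{|C|}(1-\pi_0)^{m-|C|}$, and the marginal posterior inclusion
probability of feature $i$ sums the normalized posterior over
configurations containing $i$. Defaults $\pi_0 = 10^{-3}$, $v = 30$
(roughly $N\sigma^2$ for a well-powered GWAS), $k = 3$: the upstream
literature defers these to its implementation, so they are documented
assumptions here, and the enumeration is verified exactly against a
brute-force posterior over all $2^m$ configurations for $m \le 4$.

Credible sets rank features by PIP (ties broken by feature id) and
accumulate normalized posterior mass to the 90% level, with the null
configuration competing at its posterior mass — so a null region yields an
empty credible set rather than a set of noise features. Features with
PIP ≥ 0.9 are flagged candidate causal. Expression and splicing features
are fine-mapped in separate runs, and only per-tissue PIPs (plus a
max-over-tissues summary in the report) are produced.

# The synthetic-data generator

The generator exists so that every downstream contract is checkable with no
external data; its defaults are the package's fixed study conditions.

**Genotypes.** Haplotypes are drawn from a Gaussian copula with block-AR(1)
latent correlation ($\rho$ per block) and thresholded at $\Phi^{-1}(MAF)$;
dosages are the sum of two independent haplotypes, hence marginally
Binomial(2, MAF) with LD shared across haplotypes. This makes the implied
dosage correlation computable by 1-D numerical integration, which the test
suite uses as an oracle. Blocks are 3 Mb apart so ±2 Mb conditioning
windows never span blocks. Real LD is of course messier (no clean block
boundaries, long-range structure, strand ambiguity); block-AR(1) is chosen
because it makes the linear-algebra contracts exactly checkable, not
because it is realistic.

**Weight models.** Each gene receives a sparse weight vector (default 2
causal SNPs) in one block, shared across tissues up to Gaussian noise
(SD 0.1) — mimicking the strong cross-tissue eQTL sharing of
shrinkage-refined multi-tissue models without implementing the shrinkage —
plus 1–5 intron features with their own sparse weights in the same block.
The tissue roster is `breast` plus generic tissues, 11 by default to match
the breast-cancer-relevant roster size of the motivating analysis.

**Summary statistics.** Causal genes act on the log-odds scale with effect
$\alpha$ per SD of genetic feature score (default 0.05, which at the
default 30,882 cases / 115,468 controls puts the causal SNP z-scores near
8 — comfortably genome-wide significant, as the motivating study's loci
are). The fast *direct* sampler draws, per block,
$z \sim N\!\left(\tfrac{\sqrt{N_{eff}}}{2} R \lambda,\ R\right)$ with
$\lambda$ the joint standardized log-odds effects and
$N_{eff} = 4/(1/n_{case} + 1/n_{ctrl})$; the $\sqrt{N_{eff}}/2$ constant
is fixed by the logistic score test, since
$N\varphi(1-\varphi) = N_{eff}/4$ at case fraction $\varphi$. The *individual*
sampler simulates a cohort, draws a logistic phenotype, and computes
per-SNP score-test z-scores; the two agree in expectation, which the test
suite verifies — the slow sampler is the oracle for the fast one. The
generator does not emulate imputation-panel uncertainty, X-chromosome
dosages, population stratification, or case-control ascertainment beyond
the effective-sample-size approximation, so passing tests demonstrate
correctness of the statistical machinery under the stated model, not
robustness to those real-data complications.

**Scenarios.** `make_fixtures()` writes complete input bundles: `null`
(2,000 genes, no signal — FWER checks), `single_gene` / `multi_tissue` /
`splicing_only` (one or three causal genes, expression- or splicing-driven),
`mediation` (a causal gene whose sole eQTL is also the GWAS index SNP),
`finemap_pair` (two genes in one block with predicted-expression
correlation above 0.5, one causal), and `masked_snps` (25% of model SNPs
withheld from the summary statistics to exercise imputation).

# Problem sizes and determinism

The test suite and acceptance script use: 20,000 replicates for the ACAT
type-I error (K = 11); 5,000 null features for TWAS calibration; 100
replicates at n = 5,000 for the summary-vs-individual oracle; 100 seeds for
the mediation and credible-set recovery rates; and 20 seeds of a 2,000-gene
null pipeline (3 tissues, 1–3 introns per gene, fine-mapping stage off —
the family-wise error question concerns the Bonferroni gate) for FWER
control. These sizes are the package's choices balancing Monte-Carlo error
against runtime.

One calibration note on the null-pipeline check: with two test universes of
2,000 genes each gated at family-wise $\alpha = 0.05$, the probability that
a seed is entirely clean is about
$[1 - 0.05]\times[1-0.05]$-scale, i.e. roughly 0.90–0.92 — so a small
fraction of dirty seeds is the *expected* behavior of a correctly
calibrated pipeline, not evidence of inflation; per-universe family-wise
error remains at its nominal 5%.

All analysis stages are deterministic given their inputs; randomness lives
only in the generators, which are reproducible given a seed. Re-running a
pipeline with the same configuration yields byte-identical reports.

# Worked example

```{r, eval = FALSE}
library(mtwas)

fx <- make_fixtures(tempdir(), "single_gene", seed = 2)
cfg <- pipeline_config(
  sumstats = fx$paths$sumstats, weights = fx$paths$weights,
  intron_map = fx$paths$intron_map, ld = fx$paths$ld_dir,
  index_snps = fx$paths$index_snps, outdir = file.path(tempdir(), "out"))
rep <- run_pipeline(cfg)
print(rep)
summary(rep)
subset(rep$report, IDENTIFIED)
```

# Known limitations

* The LD model is block-diagonal AR(1); conclusions about behavior under
  pathological real-world LD (e.g. mega-base haplotypes) require a real
  reference panel.
* Meta-analysis assumes non-overlapping studies; sample-overlap correction
  is out of scope.
* The reverse-mediation OR reconstruction holds SEs fixed under
  conditioning; for strongly collinear loci the adjusted SE would in truth
  grow, making the reported direct effects slightly anti-conservative.
* Fine-mapping priors ($\pi_0$, $v$) are not estimated from data, and
  cross-tissue evidence is summarized only as a per-gene maximum PIP.
* Weight-model training (fine-mapping of cis-QTL and multivariate
  shrinkage) is consumed, not implemented: models arrive as weight tables.
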