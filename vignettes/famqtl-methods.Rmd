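---
title: "Prioritizing families for rare-variant discovery: models and methods"
author: "famqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing families for rare-variant discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The design problem

Rare variants of large effect are, almost by definition, carried by only a
handful of unrelated individuals, which makes population-based association
underpowered and expensive: every rare variant in every sample is a test.
Extended families change the arithmetic. Once a rare allele enters a family
through a founder, Mendelian transmission can spread it to tens of
relatives, so a single family can concentrate enough carriers to detect the
allele's effect — provided one knows *which* family to sequence and *where*
in the genome to look.

`famqtl` implements a three-stage prioritization strategy for quantitative
traits in a sample of extended families:

1. **Oligogenic segregation analysis**, run on each family separately,
   estimates how many quantitative trait loci (QTLs) each family is likely
   to harbor, using phenotypes and pedigree structure only. Families
   estimated to carry at least one QTL more than the average of the other
   families are prioritized.
2. **Variance-components linkage** in the prioritized family localizes the
   excess signal: each gene position with identity-by-descent (IBD)
   information is tested, and regions with at least modest evidence of
   linkage (LOD ≥ 0.60, pointwise p = 0.05) are carried forward.
3. **Rare-variant filtering and measured-genotype association**: within a
   1-Mbp window around each linked gene, variants that entered the family
   through at most two founders and have at least five copies among the
   family's members are tested as fixed covariates in the family model,
   with Bonferroni correction over the candidates actually tested, and the
   linkage LOD is recomputed with the variant in the model to measure how
   much of the signal it explains.

The package also contains a synthetic-data generator that produces whole
studies of this shape — pedigrees, gene-dropped variants, covariates,
traits and a truth record — so the entire pipeline can be exercised and
calibrated without any external data.

## The oligogenic trait model and its sampler

The trait is modeled as

$$ Y = \mu + X\beta + \sum_{i=1}^{k} Q_i \alpha_i + e, $$

where $X$ collects the covariates (Sex, Age, Smoking by default), $Q_i$ is
the design matrix of the additive and dominance codings of the $i$-th QTL
genotype ($g_i - 1$ and $\mathbf{1}[g_i = 1]$ for $g_i \in \{0,1,2\}$),
$\alpha_i = (a_i, d_i)$ its effects, and $e$ i.i.d. normal residuals with
variance $\sigma^2_e$. Crucially, the number of QTLs $k$ is itself a
parameter: `run_segregation()` samples the joint posterior of
$(k, \mu, \beta, \{q_i, a_i, d_i, g_i\}, \sigma^2_e)$ by reversible-jump
MCMC.

**Genotype representation.** Each QTL's genotypes are represented by a
descent graph: one binary allele per founder allele slot and one
segregation indicator per meiosis. Genotypes are obtained by dropping the
founder alleles through the indicators, so every sampled configuration is
Mendelian-consistent *by construction* — no peeling or post-hoc
consistency check is needed, and the representation is valid for arbitrary
(including looped) pedigrees.

**Priors.** $k \sim \text{Poisson}(\lambda = 2)$ truncated to
$\{0,\dots,k_{\max}=8\}$; $a_i, d_i \sim N(0, \tau^2)$ with $\tau^2$ the
empirical trait variance (scale-adapted, weakly informative); allele
frequencies $q_i \sim \text{Beta}(1,1)$ restricted to $(0.005, 0.995)$;
$\mu, \beta$ flat; $\sigma^2_e \sim$ Inverse-Gamma$(0.5,\,0.5\,\widehat{\mathrm{Var}}(Y))$.

**Moves per iteration.** (a) a joint conjugate update of
$(\mu,\beta,\{a_i,d_i\})$ given genotypes and $\sigma^2_e$; (b) a conjugate
update of $\sigma^2_e$; (c) per QTL, Metropolis sweeps over founder alleles
and segregation indicators, with allele changes propagated selectively to
the descendants that actually inherit the flipped copy; (d) a conjugate
Beta update of each $q_i$ from its founder alleles; (e) one birth/death
reversible-jump move. Birth proposals draw all new-QTL parameters from
their priors and genotypes by gene drop, so the proposal density cancels
the prior and the acceptance ratio reduces to the likelihood ratio times
$p(k+1)/p(k)$ (the uniform-death/append-birth bookkeeping cancels against
component exchangeability, and the Jacobian is 1). With the likelihood
forced constant this chain must reproduce the truncated Poisson prior on
$k$ exactly — the test suite verifies this with a chi-square
goodness-of-fit check, which is a sharp end-to-end test of the
trans-dimensional acceptance ratios.

**Outputs.** The posterior mean of $k$ is the "expected number of QTLs"
(the fractional per-family counts imply a mean, not a mode). Variance
shares are computed per posterior sample as empirical (realized) variances
— e.g. the QTL share is
$\widehat{\mathrm{Var}}(\sum_i Q_i\alpha_i)/\widehat{\mathrm{Var}}(Y)$ —
rather than theoretical Hardy–Weinberg variances, because genotype
frequencies inside one family need not match population frequencies.
Covariate shares are attributed marginally per covariate. Heritability is
defined as the QTL share of the variance not explained by covariates,
$100\,\mathrm{QTL}\%/(\mathrm{QTL}\% + \mathrm{Residual}\%)$.

**Prioritization.** `per_family_qtl_counts()` reruns the sampler on each
family alone (the seed is reset per family so identical families receive
identical chains); `excess_qtls()` subtracts the mean count of the other
families; `prioritize_families()` selects families with excess ≥ 1.0.

**Chain settings.** Defaults are burn-in 2000, 10000 retained samples,
thinning 5. The per-family runs in the package's own test suite use
burn-in 3000 and 2000 × 5 retained iterations, which at family sizes of
73–128 give posterior-mean QTL counts stable to roughly ±0.1; these sizes
were chosen as the package's standard desk-scale operating point.

**Internal ordering.** Individuals are canonically reordered (ancestral
depth, then id) before the chain runs, so the posterior — and, with a
fixed seed, the exact sample path — is invariant to permuting the input
rows.

## Variance-components linkage

At a gene position with fully informative IBD, the trait covariance among
family members is modeled as

$$ \Omega = 2\Phi\,\sigma^2_a + \Pi\,\sigma^2_q + I\,\sigma^2_e, $$

with $\Phi$ the kinship matrix, $\Pi$ the realized locus-specific IBD
sharing matrix, and maximum-likelihood (not REML) fitting so that LOD
scores are ratios of maximized likelihoods:
$\mathrm{LOD} = (\ell_{\text{full}} - \ell_{\sigma^2_q = 0})/\ln 10$,
floored at 0. Fixed effects are profiled out by generalized least squares
inside the variance optimization; variances are optimized on the log scale
from fixed deterministic starts, and every subset of components clamped to
zero is refit explicitly so boundary solutions are found exactly rather
than approached asymptotically. Families are independent, so $\Omega$ is
block-diagonal and all computations run per family block.

Because $\sigma^2_q$ is constrained non-negative, the null distribution of
$2\ln(10)\,\mathrm{LOD}$ is the boundary mixture
$\tfrac12\chi^2_0 : \tfrac12\chi^2_1$, giving
$p = \tfrac12 P(\chi^2_1 > 2\ln(10)\,\mathrm{LOD})$ and $p = 1$ at LOD 0.
Under this convention LOD 0.60 corresponds to a pointwise p of 0.05 (to two
decimals), which is the threshold used to define linked regions. The
$\tfrac12$-mixture convention was adopted because it reproduces that
anchor; the package reports the conversion at two decimals.

Covariates are screened once per trait in the polygenic-only model:
each of Sex, Age and Smoking is retained whenever its Wald p-value is
below 0.10, and the retained set is used for all downstream fits.

$\Pi$ always comes from recorded descent (the generator's truth), never
from marker data: the analysis explicitly assumes fully informative IBD at
gene positions, and multipoint IBD estimation is out of scope.

## Variant filtering and association

Linked regions are half-open 1-Mbp windows $[c - 5\times10^5, c + 5\times10^5)$
centered at the gene position, clipped at position 1. Within a window,
`filter_candidates()` keeps variants that enter the family through at most
2 founders (a homozygous founder counts once; carriers with no founder
carrier trigger a Mendelian-inconsistency warning), have at least 5 copies
of the rare allele among the family's members, and are rare (MAF < 5%) in
the combined sample. "Copies" counts alleles (a homozygote contributes 2);
the carrier count is reported alongside, since for rare variants whose
carriers are all heterozygous the two coincide.

Association always retains the polygenic component ($2\Phi$ plus identity):
a naive unrelated-sample regression would inflate type I error among
relatives. The SNP enters additively (0/1/2) as a fixed covariate and is
tested by likelihood ratio, $p = P(\chi^2_1 > 2\Delta\ell)$. Monomorphic
scopes (e.g. zero copies outside the discovery family) report NA across
all statistics. The linkage LOD is recomputed with the SNP in the model
(`adjusted_lod()`); a collapse of the adjusted LOD toward zero means the
variant explains the linkage signal. The "variance due to SNP" is
$100\,\hat b^2 \widehat{\mathrm{Var}}(g)/\widehat{\mathrm{Var}}(Y)$ within
scope — the total-phenotypic-variance convention, chosen for
interpretability and documented because a covariate-adjusted denominator
would also have been defensible. Bonferroni correction uses the number of
candidate variants actually tested for that trait in that run, recomputed
per run. For candidate pairs whose carrier sets overlap by at least half
of the smaller set, each variant is retested conditional on the other;
identical genotype vectors are flagged collinear rather than tested.

## What the synthetic generator emulates

`simulate_study()` produces studies shaped like an eight-family
extended-pedigree exome study:

* **Pedigrees**: 8 families of 73–128 members over 5 generations, grown
  from one or two founding couples with mean sibship 3 and spouses
  marrying in as founders (probability 0.7 per non-final-generation
  child), giving founder fractions of 20–40%. Five generations (rather
  than fewer) are needed so that a single founder's allele can plausibly
  spread to the tens of copies observed in deep real families; with 3–4
  founding couples per family no single lineage is large enough.
* **Variants**: each gene in a 48-gene, 3-chromosome map gets an
  independent descent pattern per family (genes are treated as unlinked —
  inter-gene linkage disequilibrium is *not* emulated). Family-private
  functional variants enter through one founder and are conditioned to
  reach at least 20 copies in the target family (bounded redraws of the
  locus's segregation pattern), emulating rare alleles that entered the
  family several generations ago and spread — the regime the design
  targets, in which a causal rare allele reaches tens of copies in a
  ~128-member family. Shared variants give each founder allele an independent small
  carrier probability (default 1.2%), so they appear in a subset of
  families through few founders. Sixty nonfunctional rare variants (a mix
  of private and shared) provide the multiple-testing background.
* **Default trait architecture**: the first trait has two private
  large-effect variants in family "7" with additive effects 3.0 and 2.0
  residual-SD units — each then explains roughly 25–35% of that family's
  variance, matching the per-variant shares the strategy is designed to
  detect. The effects are deliberately *unequal*: two disjoint carrier
  sets with exactly equal effects form a single merged QTL (the carrier
  union with the common effect) that the segregation model cannot
  distinguish from the pair, an identifiability degeneracy that real
  effect-size heterogeneity removes. The second trait has one private
  variant of effect 1.2 (a weak-signal case). Both traits also receive a
  small-effect shared variant.
* **Covariates**: Sex from the pedigree; Age from generation bands
  (20–32 in the youngest up to 84–96 in the oldest) plus uniform noise;
  Smoking Bernoulli(0.3), optionally age-dependent
  (`age_confounding = TRUE`) to give the covariate screen a confounded
  case. Default covariate effects put roughly 1–10% of trait variance on
  each covariate. Residual SD is 1 (the trait's unit).
* **Reproducibility**: all randomness derives from one master seed via
  fixed per-stage offsets (pedigrees, descent, variants, covariates,
  traits), so a study is a pure function of its configuration and seed.

What the generator does **not** emulate: marker-based (partially
informative) IBD, linkage disequilibrium between genes, genotyping error,
population stratification, ascertainment on trait values, and binary
traits. Passing tests on these data therefore demonstrate the pipeline's
behavior under clean Mendelian transmission and fully informative IBD; on
real data, IBD estimation error and LD would dilute both the linkage and
the attribution steps.

## Numerical choices and degenerate inputs

* Variance optimization runs on $\log\sigma^2$ with L-BFGS-B from fixed
  deterministic starts (no randomness), plus explicit zero-clamped refits
  of every kernel subset; `fit_vc()` is therefore deterministic given its
  inputs, and nested fits cannot invert (the LOD is floored at 0 against
  residual optimizer noise).
* Missing-parent code "0", sex codes 1/2 only; pedigrees with exactly one
  recorded parent, absent parents, inconsistent parent sexes, or cycles
  are rejected with the offending individual named.
* Windows are half-open with 1-based coordinates, so a variant exactly at
  the right edge is excluded and ties are deterministic.
* The rare allele is the VCF ALT allele throughout the generator; in
  `filter_candidates()` commonness is judged on the combined sample
  (minor-allele frequency), guarding against ALT/REF flips in imported
  data.
* Zero trait variance, empty posteriors, monomorphic genotypes, unknown
  family ids and misaligned vectors raise immediate, specific errors
  rather than propagating NaNs.

## Known limitations

* The per-family expected QTL count has a heavy-tailed null distribution:
  occasionally a pure-noise family supports a spurious QTL partition worth
  20–25% of variance, and a null family can reach counts near 2. The
  excess-QTL threshold of 1.0 absorbs most but not all of this; across
  repeated simulated studies the prioritization occasionally misses the
  seeded family or adds a false one. This mirrors the method's real
  operating characteristics rather than an implementation artifact — the
  prioritization stage is a screen, not a test.
* Two same-trait QTLs with similar effects in one family are partially
  merged by the sampler (posterior mass on $k$ between 1 and the true
  count), so per-family counts are conservative.
* Single-family LOD scores at desk-scale family sizes are noisy; null
  genes can exceed the 0.60 screen (by design — it is a pointwise 0.05
  threshold), and occasionally outrank the causal gene. The downstream
  association stage, not the scan, carries the error control.
* The association effect estimate in the discovery family is subject to
  winner's-curse inflation; cross-family replication (`"others"` scope) is
  the unbiased read-out.
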