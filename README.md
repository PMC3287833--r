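# famqtl — family prioritization for rare-variant discovery

`famqtl` implements a family-based design strategy for finding rare
variants with large effects on quantitative traits. Sequencing every
member of every family in a study is expensive, and testing every rare
variant everywhere drowns true signals in multiple testing. The strategy
implemented here spends resources where rare alleles concentrate: it first
asks *which family* is likely to harbor extra trait loci, then *where* in
that family's genome the signal sits, and only then tests the handful of
rare variants that could explain it. It is aimed at statistical
geneticists working with extended pedigrees and quantitative traits.

## The model

The trait is modeled oligogenically,

```
Y = mu + X beta + sum_i Q_i alpha_i + e,        e ~ N(0, sigma2_e)
```

where `Q_i` codes the additive and dominance components of the i-th QTL
genotype and the number of QTLs `k` is itself a parameter, sampled by
reversible-jump MCMC with a descent-graph genotype representation
(Mendelian consistency by construction). Running the sampler on each
family separately gives per-family expected QTL counts; families with at
least one QTL more than the average of the others are prioritized.

Follow-up uses variance-components linkage,
`Omega = 2*Phi*sigma2_a + Pi*sigma2_q + I*sigma2_e`, at gene positions
with fully informative identity-by-descent sharing;
`LOD = (loglik_full − loglik_null)/ln 10`, with pointwise p-values from
the boundary mixture `½χ²₀ : ½χ²₁` (LOD 0.60 ↔ p 0.05). Rare variants in
1-Mbp windows around linked genes that entered the family through at most
two founders with at least five copies are tested as fixed covariates in
the polygenic model (measured-genotype association, likelihood-ratio
test), with Bonferroni correction over the candidates actually tested;
re-fitting the linkage model with the variant as covariate measures how
much of the LOD it explains.

A synthetic-data module generates complete studies of this shape — eight
extended families of 73–128 members, family-private rare variants entering
through single founders and gene-dropped with recorded descent, covariates
and traits under the model above, plus a truth record — so the whole
pipeline runs and can be validated with no external data.

## Worked example

```r
library(famqtl)

study <- simulate_study(sim_config(), seed = 1)
study
#> Simulated study: 8 families, 756 individuals, 65 variants, 48 genes
#>   traits: Q1, Q2

## which family harbors excess QTLs for trait Q1?
y     <- setNames(study$pheno$Q1, study$pheno$id)
covs  <- study$pheno[, c("Sex", "Age", "Smoking")]
counts <- per_family_qtl_counts(y, covs, study$pedigrees,
            seg_settings(burnin = 3000, n_samples = 2000, thin = 5), seed = 1)
round(counts, 2)
#>    1    2    3    4    5    6    7    8
#> 0.69 0.58 0.91 1.58 0.50 0.82 2.15 0.98
round(excess_qtls(counts, "7"), 2)   # +1.29 QTLs vs the other families
prioritize_families(counts)          # "7"

## family-specific linkage scan in the prioritized family
ret  <- screen_covariates(y, covs, study$pedigrees)   # Sex, Age, Smoking
scan <- scan_genes(study, "Q1", scope = "7", covariates = ret)
head(scan[order(-scan$lod), c("gene", "lod", "pvalue")], 2)
#>  gene      lod       pvalue
#>   G07 9.213143 3.666462e-11
#>   G16 3.433637 3.496980e-05

## rare variants in the linked windows, filtered by founder entry and copies
cands <- collect_candidates(linked_regions(scan), study)
cands[, c("variant_id", "gene_context", "copies_in_family", "entering_founders")]
#>  variant_id gene_context copies_in_family entering_founders
#>        C1S1          G07               24                 1
#>        C1S2          G16               20                 1

## association and linkage-signal attribution across scopes
cross_family_replication("C1S1", study, "Q1", "7", covariates = ret)
#>   scope n_copies n_founder_entries   pvalue lod_unadjusted lod_adjusted pct_variance_snp
#>  family       24                 1 2.21e-17           9.21        0.000             49.1
#>  others        0                 0       NA             NA           NA               NA
#>     all       24                 1 6.18e-35          16.30        0.107             19.8
```

Reading the output: family 7's expected QTL count (2.15) exceeds the mean
of the other families by 1.29, so it is prioritized; its family-specific
scan puts the two highest LODs exactly at the genes carrying the two
seeded private variants; both variants survive the founder-entry and
copy-count filters; and variant `C1S1` is strongly associated
(p = 2.2e-17 in the family), private to family 7 (the `others` scope is
monomorphic, reported NA), and absorbs the linkage signal completely
(LOD 9.21 → 0.00 after adjustment), explaining 49% of the family's trait
variance. `run_pipeline()` chains all of these stages (plus the joint
variance-partition table) behind one configuration object, and
`render_report()` writes the three report tables as TSV.

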