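test_that("measured-genotype test calibrates under permutation", {
  set.seed(61)
  cfg <- sim_config(n_families = 1, family_size_range = c(32, 38),
                    n_generations = 4)
  ped <- simulate_pedigree(cfg, 1)
  n <- nrow(ped)
  repeat {
    g <- gene_drop(ped, founders(ped)[1])$genotype
    if (sum(g) >= 6) break
  }
  y0 <- stats::setNames(rnorm(n), ped$id)
  hits <- 0L
  for (r in 1:200) {
    yp <- stats::setNames(sample(y0), ped$id)
    p <- measured_genotype_test(yp, NULL, g, ped)$pvalue
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / 200, 0.025)
  expect_lte(hits / 200, 0.075)
})

test_that("a strong causal variant is detected in its family", {
  st <- small_study(seed = 71)
  fam <- st$truth$seeded_family
  vid <- st$truth$functional$variant[1]
  ids <- st$pedigrees[[fam]]$id
  y <- stats::setNames(st$pheno[ids, "Q1"], ids)
  X <- st$pheno[ids, c("Sex", "Age", "Smoking")]
  mt <- measured_genotype_test(y, X, st$genotypes[ids, vid],
                               st$pedigrees[fam])
  expect_lt(mt$pvalue, 1e-3)
  expect_equal(mt$flag, "ok")
})

test_that("monomorphic scopes return NA and allele coding does not matter", {
  st <- small_study(seed = 71)
  fam <- "1"
  ids <- st$pedigrees[[fam]]$id
  y <- stats::setNames(st$pheno[ids, "Q1"], ids)
  mono <- stats::setNames(rep(0L, length(ids)), ids)
  mt <- measured_genotype_test(y, NULL, mono, st$pedigrees[fam])
  expect_true(is.na(mt$pvalue))
  expect_equal(mt$flag, "monomorphic")

  set.seed(2)
  g <- gene_drop(st$pedigrees[[fam]], founders(st$pedigrees[[fam]])[1])$genotype
  a <- measured_genotype_test(y, NULL, g, st$pedigrees[fam])
  b <- measured_genotype_test(y, NULL, 2L - g, st$pedigrees[fam])
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-5)
  expect_equal(a$effect, -b$effect, tolerance = 1e-4)
})

test_that("Bonferroni selection follows the corrected threshold", {
  expect_identical(
    bonferroni_significant(c(v1 = 2.0e-4), m = 216), "v1")
  expect_identical(
    bonferroni_significant(c(v1 = 6e-4), m = 85), character(0))
  expect_identical(bonferroni_significant(numeric(0), m = 5), character(0))
  expect_error(bonferroni_significant(c(v1 = 0.1), m = 0), "positive")
  expect_error(bonferroni_significant(c(v1 = 0.1, v2 = 0.2), m = 1),
               "at least")
})

test_that("carrier overlap counts carriers and their intersection", {
  ga <- c(1L, 0L, 2L, 0L); gb <- c(1L, 1L, 0L, 0L)
  ov <- carrier_overlap(ga, gb)
  expect_equal(ov, list(n_a = 2L, n_b = 2L, n_both = 1L))
  expect_equal(carrier_overlap(ga, ga)$n_both, 2L)
  expect_equal(carrier_overlap(ga, c(1L, 0L, 0L, 1L))$n_both, 1L)
  expect_equal(carrier_overlap(c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L))$n_both, 0L)
})

test_that("conditional tests control for a second variant", {
  st <- small_study(seed = 81)
  fam <- st$truth$seeded_family
  ids <- st$pedigrees[[fam]]$id
  y <- stats::setNames(st$pheno[ids, "Q1"], ids)
  vid <- st$truth$functional$variant[1]
  g <- st$genotypes[ids, vid]

  # collinear pair is flagged
  ct <- conditional_test(y, NULL, g, g, st$pedigrees[fam])
  expect_equal(ct$flag, "collinear")
  expect_true(is.na(ct$pvalue))

  # constant adjusting genotype reduces exactly to the unconditional test
  const <- stats::setNames(rep(0L, length(ids)), ids)
  ct2 <- conditional_test(y, NULL, g, const, st$pedigrees[fam])
  mt <- measured_genotype_test(y, NULL, g, st$pedigrees[fam])
  expect_identical(ct2$pvalue, mt$pvalue)
})

test_that("adjusted LOD equals unadjusted for a constant genotype", {
  st <- small_study(seed = 81)
  fam <- st$truth$seeded_family
  ids <- st$pedigrees[[fam]]$id
  y <- stats::setNames(st$pheno[ids, "Q1"], ids)
  gene <- st$truth$functional$gene[1]
  Pi <- true_ibd_matrix(st$descent[[gene]][ids, ])
  const <- stats::setNames(rep(0L, length(ids)), ids)
  lods <- adjusted_lod(y, NULL, const, Pi, st$pedigrees[fam])
  expect_identical(lods[["unadjusted"]], lods[["adjusted"]])
})

test_that("cross-family replication partitions the sample across scopes", {
  st <- small_study(seed = 71)
  fam <- st$truth$seeded_family
  vid <- st$truth$functional$variant[1]
  rep3 <- cross_family_replication(vid, st, "Q1", fam)
  expect_equal(rep3$scope, c("family", "others", "all"))
  expect_equal(rep3$n[1] + rep3$n[2], rep3$n[3])
  expect_equal(rep3$n_copies[1] + rep3$n_copies[2], rep3$n_copies[3])
  # family-private variant: the others scope is monomorphic, reported NA
  expect_equal(rep3$n_copies[2], 0)
  expect_true(is.na(rep3$pvalue[2]))
  expect_false(is.na(rep3$pvalue[1]))
  expect_true(all(stats::na.omit(rep3$pct_variance_snp) >= 0 &
                  stats::na.omit(rep3$pct_variance_snp) <= 100))
})

test_that("variance attribution to a SNP is shift-invariant and bounded", {
  set.seed(5)
  g <- rbinom(60, 2, 0.2)
  y <- 0.8 * g + rnorm(60)
  pct <- variance_due_to_snp(0.8, g, y)
  expect_gt(pct, 0); expect_lte(pct, 100)
  expect_equal(pct, variance_due_to_snp(0.8, g, y + 100))
  expect_equal(variance_due_to_snp(0, g, y), 0)
  expect_error(variance_due_to_snp(1, g, rep(1, 60)), "zero variance")
})
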