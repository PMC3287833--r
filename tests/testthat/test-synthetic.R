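test_that("simulated pedigrees respect the configured conditions", {
  cfg <- sim_config()
  set.seed(1)
  ped <- simulate_pedigree(cfg, 1)
  n <- nrow(ped); nf <- length(founders(ped))
  expect_gte(n, 73); expect_lte(n, 128)
  expect_gte(nf / n, 0.20); expect_lte(nf / n, 0.40)

  # a [3,3] two-generation configuration yields a trio
  tiny <- sim_config(n_families = 1, family_size_range = c(3, 3),
                     n_generations = 2)
  set.seed(2)
  trio <- simulate_pedigree(tiny, 1)
  expect_equal(nrow(trio), 3L)
  expect_length(founders(trio), 2L)

  # determinism under a fixed seed
  set.seed(5); a <- simulate_pedigree(cfg, 2)
  set.seed(5); b <- simulate_pedigree(cfg, 2)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("gene_drop transmits alleles Mendelianly with recorded descent", {
  trio <- ped_trio()
  set.seed(1)
  gd0 <- gene_drop(trio, character(0))
  expect_true(all(gd0$genotype == 0))

  expect_error(gene_drop(trio, "c1"), "not founders")

  # binomial oracle: child inherits the father's rare allele w.p. 1/2
  set.seed(2)
  hits <- replicate(1e4, gene_drop(trio, "p1")$genotype[["c1"]])
  expect_lt(abs(mean(hits) - 0.5), 0.02)

  # founder copies equal the number of entering founders by construction
  set.seed(3)
  ped <- simulate_pedigree(sim_config(family_size_range = c(40, 60)), 1)
  ef <- founders(ped)[1:2]
  gd <- gene_drop(ped, ef)
  expect_equal(sum(gd$genotype[founders(ped)]), 2L)
})

test_that("study genotypes are Mendelian-consistent for every variant", {
  st <- small_study(seed = 11)
  for (f in names(st$pedigrees)) {
    ped <- st$pedigrees[[f]]
    g <- st$genotypes[ped$id, , drop = FALSE]
    kid <- !is.na(ped$father)
    gf <- g[match(ped$father[kid], ped$id), , drop = FALSE]
    gm <- g[match(ped$mother[kid], ped$id), , drop = FALSE]
    gc <- g[kid, , drop = FALSE]
    # a child's count is bounded by what each parent can transmit
    expect_true(all(gc <= (gf >= 1) + (gm >= 1)))
    expect_true(all(gc >= (gf == 2) + (gm == 2) - 1))
    expect_true(all(gc[gf == 0 & gm == 0] == 0))
  }
})

test_that("realized IBD matches forced sharing and kinship expectation", {
  trio <- ped_trio()
  set.seed(4)
  gd <- gene_drop(trio)
  Pi <- true_ibd_matrix(gd$descent)
  expect_equal(Pi["p1", "p2"], 0)        # founder pair never shares
  expect_equal(Pi["p1", "c1"], 0.5)      # parent-offspring always 0.5
  expect_equal(diag(Pi), setNames(rep(1, 3), trio$id))

  # E[Pi] over repeated drops equals 2*phi for a sib pair
  quart <- ped_quartet()
  set.seed(8)
  pis <- replicate(1e4, true_ibd_matrix(gene_drop(quart)$descent)["s1", "s2"])
  expect_true(all(pis %in% c(0, 0.5, 1)))
  expect_lt(abs(mean(pis) - 2 * 0.25), 0.02)
})

test_that("traits follow the generative model", {
  st <- small_study(seed = 21)
  cfg <- st$config
  ids <- st$pheno$id

  # regression on the truth genotypes recovers the configured effect
  vid <- st$truth$functional$variant[1]
  fam <- st$truth$functional$families[1]
  fids <- st$pedigrees[[fam]]$id
  fit <- stats::lm(st$pheno[fids, "Q1"] ~ st$genotypes[fids, vid] +
                     Sex + Age + Smoking, data = st$pheno[fids, ])
  est <- summary(fit)$coefficients[2, ]
  expect_lt(abs(est["Estimate"] - cfg$qtl_specs$a[1]), 3 * est["Std. Error"])

  # null model: with all effects zero the trait is N(mu, residual_sd^2)
  cfg0 <- cfg
  cfg0$qtl_specs <- cfg$qtl_specs[0, ]
  cfg0$covariate_effects <- list(Q1 = c(Sex = 0, Age = 0, Smoking = 0))
  cfg0$mu <- 1.5
  set.seed(9); y0 <- simulate_traits(st, cfg0)[, "Q1"]
  expect_lt(abs(mean(y0) - 1.5), 4 * cfg$residual_sd / sqrt(length(y0)))
  # determinism
  set.seed(9); y1 <- simulate_traits(st, cfg0)[, "Q1"]
  expect_identical(y0, y1)

  # variance decomposition: QTL contribution share is close to the share
  # implied by the generative components
  qc <- rep(0, length(ids))
  fun <- st$truth$functional
  for (r in seq_len(nrow(fun)))
    qc <- qc + fun$a[r] * (st$genotypes[ids, fun$variant[r]] - 1)
  vy <- stats::var(st$pheno$Q1)
  expect_lt(abs(stats::var(qc) / vy -
                (1 - stats::var(st$pheno$Q1 - qc) / vy -
                 2 * stats::cov(qc, st$pheno$Q1 - qc) / vy)), 1e-9)
})

test_that("studies round-trip through disk exactly", {
  st <- small_study(seed = 31)
  d <- tempfile()
  write_study(st, d)
  back <- read_study(d)
  expect_identical(back$genotypes[rownames(st$genotypes),
                                  colnames(st$genotypes)],
                   st$genotypes)
  expect_equal(back$pheno$Q1, st$pheno$Q1)
  # VCF allele counts match the genotype sums (VCF is position-sorted)
  expect_equal(colSums(back$genotypes)[colnames(st$genotypes)],
               colSums(st$genotypes))
  # truth record lists exactly the configured functional variants
  expect_setequal(back$truth$functional$variant,
                  st$truth$functional$variant)
  # descent labels preserved
  g1 <- st$gene_map$gene[1]
  expect_equal(unname(back$descent[[g1]]), unname(st$descent[[g1]]))
})

test_that("a one-founder variant segregates with positive variance", {
  set.seed(13)
  ped <- simulate_pedigree(sim_config(family_size_range = c(40, 60)), 1)
  ef <- founders(ped)[3]
  counts <- replicate(1e3, sum(gene_drop(ped, ef)$genotype))
  expect_gte(mean(counts), 1)
  expect_gt(stats::var(counts), 0)
})
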