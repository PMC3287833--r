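test_that("fit_vc reduces to ordinary least squares without kernels", {
  set.seed(1)
  n <- 40
  X <- cbind(x = rnorm(n))
  y <- 1 + 0.5 * X[, 1] + rnorm(n)
  fit <- fit_vc(y, X)
  ols <- stats::lm(y ~ X)
  expect_equal(fit$loglik, as.numeric(stats::logLik(ols)), tolerance = 1e-5)
  expect_equal(unname(fit$fixef), unname(stats::coef(ols)), tolerance = 1e-4)

  # a diagonal "polygenic" kernel cannot beat the OLS likelihood either
  fit2 <- fit_vc(y, X, kernels = list(polygenic = diag(n)))
  expect_equal(fit2$loglik, as.numeric(stats::logLik(ols)), tolerance = 1e-5)
})

test_that("fit_vc loglik equals the direct multivariate-normal density", {
  ped <- pedigree("f", c("a", "b", "c", "d", "e", "f"),
                  father = c(NA, NA, "a", "a", NA, "c"),
                  mother = c(NA, NA, "b", "b", NA, "e"),
                  sex = c(1, 2, 1, 2, 2, 1))
  Phi2 <- 2 * kinship_matrix(ped)
  set.seed(3)
  y <- drop(chol(0.6 * Phi2 + 0.4 * diag(6)) %*% rnorm(6)) + 1
  fit <- fit_vc(y, kernels = list(polygenic = Phi2))
  Sigma <- fit$sigma2["polygenic"] * Phi2 + fit$sigma2["residual"] * diag(6)
  direct <- dmvn_log(y, rep(fit$fixef[1], 6), Sigma)
  expect_equal(fit$loglik, direct, tolerance = 1e-6)
})

test_that("fit_vc recovers polygenic heritability", {
  set.seed(21)
  cfg <- sim_config(n_families = 4, family_size_range = c(60, 80),
                    n_generations = 4)
  peds <- lapply(1:4, function(i) simulate_pedigree(cfg, i))
  pk <- famqtl:::polygenic_kernel(peds)
  n <- length(pk$ids)
  h2 <- 0.5; vtot <- 2
  set.seed(4)
  y <- as.numeric(t(chol(h2 * vtot * pk$kernel +
                           (1 - h2) * vtot * diag(n))) %*% rnorm(n))
  fit <- fit_vc(y, kernels = list(polygenic = pk$kernel), blocks = pk$blocks)
  est <- fit$sigma2["polygenic"] /
    (fit$sigma2["polygenic"] + fit$sigma2["residual"])
  expect_lt(abs(est - h2), 0.1)
})

test_that("LOD scores behave as nested likelihood ratios", {
  ped <- ped_three_gen()
  Phi2 <- 2 * kinship_matrix(ped)
  set.seed(5)
  y <- rnorm(12)
  Pi <- true_ibd_matrix(gene_drop(ped)$descent)
  full <- fit_vc(y, kernels = list(polygenic = Phi2, locus = Pi))
  null <- fit_vc(y, kernels = list(polygenic = Phi2))
  expect_gte(full$loglik, null$loglik - 1e-4)  # nesting monotonicity
  expect_gte(lod_score(full, null), 0)
  expect_equal(lod_score(null, null), 0)
  # mismatched scopes are rejected
  null2 <- fit_vc(y, covariates = cbind(x = rnorm(12)),
                  kernels = list(polygenic = Phi2))
  expect_error(lod_score(full, null2), "mismatched")
})

test_that("LOD is invariant under affine trait transformation", {
  set.seed(6)
  ped <- simulate_pedigree(sim_config(family_size_range = c(40, 60)), 1)
  Phi2 <- 2 * kinship_matrix(ped)
  gd <- gene_drop(ped, founders(ped)[1])
  Pi <- true_ibd_matrix(gd$descent)
  n <- nrow(ped)
  y <- 0.9 * (gd$genotype - 1) + rnorm(n)
  lod1 <- lod_score(fit_vc(y, kernels = list(p = Phi2, l = Pi)),
                    fit_vc(y, kernels = list(p = Phi2)))
  y2 <- -2.5 * y + 7
  lod2 <- lod_score(fit_vc(y2, kernels = list(p = Phi2, l = Pi)),
                    fit_vc(y2, kernels = list(p = Phi2)))
  expect_equal(lod1, lod2, tolerance = 1e-6)
})

test_that("LOD-to-p follows the half chi-square boundary mixture", {
  expect_equal(round(lod_to_pvalue(0.60), 2), 0.05)
  expect_equal(signif(lod_to_pvalue(5.3), 1), 4e-7)
  expect_equal(signif(lod_to_pvalue(2.02), 1), 0.001)
  expect_equal(lod_to_pvalue(0), 1)
  expect_error(lod_to_pvalue(-0.1), "non-negative")
})

test_that("covariate screening keeps strong predictors and drops null ones", {
  set.seed(7)
  cfg <- sim_config(n_families = 2, family_size_range = c(30, 40),
                    n_generations = 3)
  peds <- lapply(1:2, function(i) simulate_pedigree(cfg, i))
  ids <- unlist(lapply(peds, `[[`, "id"))
  n <- length(ids)
  kept_strong <- 0L; dropped_null <- 0L
  for (r in 1:20) {
    X <- data.frame(strong = rnorm(n), null = rnorm(n), row.names = ids)
    y <- stats::setNames(2.5 * X$strong + rnorm(n), ids)
    ret <- screen_covariates(y, X, peds)
    kept_strong <- kept_strong + ("strong" %in% ret)
    dropped_null <- dropped_null + (!"null" %in% ret)
  }
  expect_equal(kept_strong, 20L)     # ~70% of variance: always retained
  expect_gte(dropped_null, 18L)      # null covariate excluded in >= 90%
  expect_identical(screen_covariates(stats::setNames(rnorm(n), ids),
                                     data.frame(row.names = ids), peds),
                   character(0))
})

test_that("scan_genes handles empty maps and missing descent", {
  st <- small_study(seed = 41)
  empty <- scan_genes(st, "Q1", scope = "1",
                      gene_map = st$gene_map[0, ])
  expect_equal(nrow(empty), 0L)
  gm <- rbind(st$gene_map[1, ],
              data.frame(gene = "NOPE", chrom = "1", pos = 999))
  expect_warning(res <- scan_genes(st, "Q1", scope = "1", gene_map = gm),
                 "no descent")
  expect_equal(nrow(res), 1L)
  expect_true(all(res$lod >= 0) && all(res$pvalue <= 1))
})
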