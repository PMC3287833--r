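# Shared fixtures and independent oracles for the test suite.

ped_trio <- function(fid = "t") {
  pedigree(fid, c("p1", "p2", "c1"),
           father = c(NA, NA, "p1"), mother = c(NA, NA, "p2"),
           sex = c(1, 2, 1))
}

# two parents, two children (full sibs)
ped_quartet <- function(fid = "q") {
  pedigree(fid, c("p1", "p2", "s1", "s2"),
           father = c(NA, NA, "p1", "p1"), mother = c(NA, NA, "p2", "p2"),
           sex = c(1, 2, 1, 2))
}

# 12-member, 3-generation pedigree containing a first-cousin pair (c1, c2):
# founding couple g1/g2; their sons m1, m2 marry founders w1, w2; each
# couple has children (the cousins) plus sibs.
ped_three_gen <- function(fid = "tg") {
  pedigree(fid,
           c("g1", "g2", "m1", "m2", "w1", "w2",
             "c1", "c2", "c3", "c4", "c5", "c6"),
           father = c(NA, NA, "g1", "g1", NA, NA,
                      "m1", "m2", "m1", "m2", "m1", "m2"),
           mother = c(NA, NA, "g2", "g2", NA, NA,
                      "w1", "w2", "w1", "w2", "w1", "w2"),
           sex = c(1, 2, 1, 1, 2, 2, 1, 2, 1, 2, 2, 1))
}

# Independent Monte-Carlo gene-dropping estimate of the kinship matrix:
# repeatedly drops uniquely labelled founder alleles and averages the
# fraction of identical-by-descent allele pairs.  Written without using
# famqtl's own gene_drop/kinship code paths.
mc_kinship <- function(ped, n_drops = 1e4) {
  n <- nrow(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  # ancestral order by repeated relaxation
  depth <- ifelse(is.na(fa), 0L, NA_integer_)
  while (anyNA(depth))
    for (i in which(is.na(depth)))
      if (!is.na(depth[fa[i]]) && !is.na(depth[mo[i]]))
        depth[i] <- max(depth[fa[i]], depth[mo[i]]) + 1L
  ord <- order(depth)
  A1 <- matrix(0L, n_drops, n); A2 <- matrix(0L, n_drops, n)
  lab <- 0L
  for (i in ord) {
    if (is.na(fa[i])) {
      A1[, i] <- lab + 1L; A2[, i] <- lab + 2L; lab <- lab + 2L
    } else {
      pick1 <- stats::runif(n_drops) < 0.5
      pick2 <- stats::runif(n_drops) < 0.5
      A1[, i] <- ifelse(pick1, A1[, fa[i]], A2[, fa[i]])
      A2[, i] <- ifelse(pick2, A1[, mo[i]], A2[, mo[i]])
    }
  }
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    ibd <- (A1[, i] == A1[, j]) + (A1[, i] == A2[, j]) +
           (A2[, i] == A1[, j]) + (A2[, i] == A2[, j])
    K[i, j] <- K[j, i] <- mean(ibd) / 4
  }
  K
}

# direct multivariate-normal log-density (independent of fit_vc internals)
dmvn_log <- function(y, mean, Sigma) {
  ch <- chol(Sigma)
  z <- backsolve(ch, y - mean, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

# small study used across association/variant tests
small_study <- function(seed = 7) {
  cfg <- sim_config(n_families = 3, family_size_range = c(35, 55),
                    n_generations = 4, seeded_family = "2",
                    traits = "Q1",
                    qtl_specs = data.frame(trait = "Q1", family = "2",
                                           n_founders = 1L, a = 2.0, d = 0,
                                           freq = NA),
                    n_null_variants = 20, min_copies_functional = 8,
                    gene_map = data.frame(gene = sprintf("G%02d", 1:10),
                                          chrom = as.character(rep(1:2, each = 5)),
                                          pos = rep(2e6 + (0:4) * 4e6, 2)))
  simulate_study(cfg, seed = seed)
}

# reduced null-scenario configuration (no functional variants)
null_sim_config <- function() {
  sim_config(n_families = 4, family_size_range = c(25, 40),
             n_generations = 4, traits = "Q1",
             qtl_specs = data.frame(trait = character(0), family = character(0),
                                    n_founders = integer(0), a = numeric(0),
                                    d = numeric(0), freq = numeric(0)),
             n_null_variants = 25,
             gene_map = data.frame(gene = sprintf("G%02d", 1:12),
                                   chrom = as.character(rep(1:2, each = 6)),
                                   pos = rep(2e6 + (0:5) * 4e6, 2)))
}
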