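#' Settings for the oligogenic segregation sampler
#'
#' Defaults follow common practice for trans-dimensional samplers at this
#' problem size: a truncated Poisson prior on the number of QTLs, effect
#' priors scaled to the empirical trait variance, and a chain long enough
#' for the QTL count to mix.
#'
#' @param burnin iterations discarded before sampling.
#' @param n_samples posterior samples retained.
#' @param thin iterations between retained samples.
#' @param k_max maximum number of QTLs (birth moves beyond it auto-reject).
#' @param lambda mean of the (truncated) Poisson prior on the QTL count.
#' @param q_range allowed range for QTL allele frequencies.
#' @return a list of settings for [run_segregation()].
#' @export
seg_settings <- function(burnin = 2000, n_samples = 10000, thin = 5,
                         k_max = 8, lambda = 2, q_range = c(0.005, 0.995)) {
  stopifnot(burnin >= 0, thin >= 1, k_max >= 1, lambda > 0,
            length(q_range) == 2, q_range[1] > 0, q_range[2] < 1,
            q_range[1] < q_range[2])
  if (n_samples < 1) stop("empty posterior: n_samples must be >= 1")
  list(burnin = as.integer(burnin), n_samples = as.integer(n_samples),
       thin = as.integer(thin), k_max = as.integer(k_max),
       lambda = lambda, q_range = q_range)
}

# canonical individual order for the sampler: families in list order, and
# within a family ancestral depth then id, so that permuting the input rows
# leaves the chain unchanged
seg_layout <- function(trait, covariates, peds) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  peds <- lapply(peds, ensure_pedigree)
  ids <- character(0); fa <- integer(0); mo <- integer(0); fam <- character(0)
  for (ped in peds) {
    o <- attr(ped, "topo")
    depth <- integer(nrow(ped))
    fidx <- match(ped$father, ped$id); midx <- match(ped$mother, ped$id)
    for (i in o) depth[i] <- if (is.na(fidx[i])) 0L else
      max(depth[fidx[i]], depth[midx[i]]) + 1L
    ord <- order(depth, ped$id)
    base <- length(ids)
    ids <- c(ids, ped$id[ord])
    pos <- integer(nrow(ped)); pos[ord] <- seq_along(ord)
    fa <- c(fa, ifelse(is.na(fidx[ord]), -1L, base + pos[fidx[ord]] - 1L))
    mo <- c(mo, ifelse(is.na(midx[ord]), -1L, base + pos[midx[ord]] - 1L))
    fam <- c(fam, ped$family[ord])
  }
  if (anyDuplicated(ids))
    stop("individual ids must be unique across families")
  y <- trait[ids]
  if (anyNA(y)) stop("trait missing for: ",
                     paste(ids[is.na(y)], collapse = ", "))
  X <- as.matrix(as.data.frame(covariates)[ids, , drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("covariates incomplete for some pedigree members")
  list(ids = ids, fa = fa, mo = mo, family = fam, y = as.numeric(y), X = X)
}

#' Oligogenic segregation analysis by reversible-jump MCMC
#'
#' Samples the posterior of an oligogenic model for a quantitative trait in
#' one or more pedigrees: the trait is the sum of an overall mean, covariate
#' effects, the additive and dominance contributions of an unknown number k
#' of QTLs, and normal residuals.  k is a parameter of the model, sampled by
#' birth/death reversible-jump moves; QTL genotypes are represented by
#' founder alleles plus segregation indicators (a descent graph), so every
#' sampled configuration is Mendelian-consistent by construction.
#'
#' @param trait named numeric vector of trait values (names are individual
#'   ids).
#' @param covariates data frame or matrix of numeric covariates with row
#'   names equal to the individual ids (e.g. Sex, Age, Smoking).
#' @param peds a [pedigree] or list of pedigrees covering all individuals.
#' @param settings see [seg_settings()].
#' @param likelihood `"normal"` for the trait model; `"constant"` replaces
#'   the likelihood by a constant so the chain targets the prior (used to
#'   validate the trans-dimensional moves).
#' @return object of class `seg_posterior`: list with `k_samples`,
#'   `share_samples` (per-sample variance shares for each covariate, the
#'   QTL total and the residual), `expected_k`, `acceptance_rates`, `n`,
#'   and the settings used.
#' @export
run_segregation <- function(trait, covariates, peds, settings = seg_settings(),
                            likelihood = c("normal", "constant")) {
  likelihood <- match.arg(likelihood)
  lay <- seg_layout(trait, covariates, peds)
  vy <- stats::var(lay$y)
  if (likelihood == "normal" && (!is.finite(vy) || vy <= 0))
    stop("trait has zero variance")
  tau2 <- if (is.finite(vy) && vy > 0) vy else 1
  res <- .seg_mcmc_cpp(lay$y, lay$X, lay$fa, lay$mo,
                       settings$lambda, settings$k_max, tau2,
                       0.5, 0.5 * tau2,
                       settings$q_range[1], settings$q_range[2],
                       settings$burnin, settings$n_samples, settings$thin,
                       likelihood == "constant")
  shares <- res$shares
  colnames(shares) <- c(colnames(lay$X), "qtl", "residual")
  structure(list(k_samples = as.integer(res$k),
                 share_samples = shares,
                 expected_k = mean(res$k),
                 acceptance_rates = res$accept,
                 n = length(lay$y),
                 trait_variance = vy,
                 settings = settings,
                 likelihood = likelihood),
            class = "seg_posterior")
}

#' @export
print.seg_posterior <- function(x, ...) {
  cat(sprintf("Oligogenic segregation posterior: n = %d, %d samples\n",
              x$n, length(x$k_samples)))
  cat(sprintf("  expected number of QTLs: %.2f\n", x$expected_k))
  invisible(x)
}

#' Variance partition from a segregation posterior
#'
#' Per posterior sample, the share of the total trait variance attributed to
#' each covariate (empirical variance of its fitted contribution over the
#' empirical trait variance), to all QTLs jointly, and to the residual; the
#' reported partition is the posterior mean of each share, in percent,
#' together with the expected QTL count and the heritability.
#'
#' @param post a `seg_posterior` from [run_segregation()].
#' @return object of class `variance_partition`: named list of percentages
#'   (one per covariate plus `qtl_pct` and `residual_pct`), `expected_k`
#'   and `heritability_pct`.
#' @export
variance_partition <- function(post) {
  stopifnot(inherits(post, "seg_posterior"))
  if (post$likelihood != "normal")
    stop("variance partition requires a chain run under the trait likelihood")
  if (!is.finite(post$trait_variance) || post$trait_variance <= 0)
    stop("trait has zero variance")
  m <- colMeans(post$share_samples) * 100
  covs <- setdiff(colnames(post$share_samples), c("qtl", "residual"))
  out <- list(covariate_pct = m[covs],
              qtl_pct = unname(m["qtl"]),
              residual_pct = unname(m["residual"]),
              expected_k = post$expected_k,
              heritability_pct = heritability(unname(m["qtl"]),
                                              unname(m["residual"])))
  class(out) <- "variance_partition"
  out
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("Variance partition (% of total trait variance):\n")
  for (nm in names(x$covariate_pct))
    cat(sprintf("  %-12s %5.1f\n", nm, x$covariate_pct[nm]))
  cat(sprintf("  %-12s %5.1f  (expected QTLs %.1f)\n", "QTL", x$qtl_pct,
              x$expected_k))
  cat(sprintf("  %-12s %5.1f\n", "Residual", x$residual_pct))
  cat(sprintf("  Heritability %5.1f\n", x$heritability_pct))
  invisible(x)
}

#' Heritability from QTL and residual variance shares
#'
#' Heritability is defined here as the ratio of the variance attributed to
#' the QTLs to the variance not explained by the covariates, expressed in
#' percent: `100 * qtl_pct / (qtl_pct + residual_pct)`.
#'
#' @param qtl_pct percent of trait variance attributed to all QTLs.
#' @param residual_pct percent of trait variance left in the residual.
#' @return heritability in percent.
#' @examples
#' heritability(46.5, 38.9)  # ~54.4
#' @export
heritability <- function(qtl_pct, residual_pct) {
  stopifnot(all(qtl_pct >= 0), all(residual_pct >= 0))
  if (any(qtl_pct + residual_pct == 0))
    stop("qtl_pct and residual_pct cannot both be zero")
  100 * qtl_pct / (qtl_pct + residual_pct)
}

#' Expected QTL count per family
#'
#' Runs the segregation analysis independently on each family (its members
#' only) and returns the posterior mean QTL count per family.  Families
#' with fewer than 3 members are excluded with a warning.  The random seed
#' is reset to `seed` before each family's chain, so identical families
#' with identical data yield identical counts.
#'
#' @inheritParams run_segregation
#' @param seed integer seed applied before each family's chain.
#' @return named numeric vector of expected QTL counts, one per family.
#' @export
per_family_qtl_counts <- function(trait, covariates, peds,
                                  settings = seg_settings(), seed = 1L) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  if (length(peds) < 2L) stop("per-family analysis needs at least 2 families")
  counts <- numeric(0)
  for (ped in peds) {
    fam <- ped$family[1]
    if (nrow(ped) < 3L) {
      warning("family ", fam, " has fewer than 3 members; excluded")
      next
    }
    ids <- ped$id
    set.seed(seed)
    post <- run_segregation(trait[ids],
                            as.data.frame(covariates)[ids, , drop = FALSE],
                            ped, settings)
    counts[fam] <- post$expected_k
  }
  counts
}

#' Excess QTL count of one family
#'
#' The family's expected QTL count minus the arithmetic mean of the counts
#' of all other families.
#'
#' @param counts named numeric vector of per-family expected QTL counts.
#' @param family family id.
#' @return signed excess count.
#' @examples
#' q1 <- c(`1` = 1.7, `2` = 1.5, `3` = 1.3, `4` = 1.7,
#'         `5` = 1.9, `6` = 1.2, `7` = 3.6, `8` = 1.1)
#' excess_qtls(q1, "7")  # ~ +2.1
#' @export
excess_qtls <- function(counts, family) {
  family <- as.character(family)
  if (length(counts) < 2L) stop("need counts for at least 2 families")
  if (!family %in% names(counts)) stop("unknown family id: ", family)
  unname(counts[family] - mean(counts[setdiff(names(counts), family)]))
}

#' Prioritize families harboring excess QTLs
#'
#' Families estimated to harbor at least `threshold` additional QTLs
#' compared to the average number in the other families are selected for
#' follow-up linkage and sequencing.
#'
#' @param counts named numeric vector of per-family expected QTL counts.
#' @param threshold minimum excess QTL count (default 1.0).
#' @return character vector of prioritized family ids (possibly empty).
#' @export
prioritize_families <- function(counts, threshold = 1.0) {
  if (length(counts) < 2L) stop("need counts for at least 2 families")
  fams <- names(counts)
  fams[vapply(fams, function(f) excess_qtls(counts, f) >= threshold,
              logical(1))]
}
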