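#' Measured-genotype association test in pedigrees
#'
#' Tests a variant by including its additive-coded genotype as a fixed
#' covariate in the polygenic variance-components model (kernel 2*Phi plus
#' identity), which keeps the type I error controlled among relatives.
#' The test is a likelihood-ratio test of the SNP effect,
#' `p = P(chisq_1 > 2 * delta loglik)`.
#'
#' @param trait named numeric vector over the tested individuals.
#' @param covariates data frame of retained covariates (row names = ids),
#'   or `NULL`.
#' @param genotype named 0/1/2 vector, additive coding.
#' @param peds [pedigree] or list of pedigrees covering the individuals.
#' @return list with `pvalue`, `effect` (fitted allele-substitution
#'   effect), `fit` (the full `vc_fit`), `null_fit`, and `flag`
#'   (`"ok"` or `"monomorphic"`; monomorphic scopes return `NA`
#'   statistics, as for scopes with zero copies).
#' @export
measured_genotype_test <- function(trait, covariates, genotype, peds) {
  pk <- polygenic_kernel(peds)
  y <- trait[pk$ids]
  g <- genotype[pk$ids]
  X0 <- if (!is.null(covariates) && NCOL(covariates) > 0)
    as.data.frame(covariates)[pk$ids, , drop = FALSE] else NULL
  if (stats::var(g) == 0)
    return(list(pvalue = NA_real_, effect = NA_real_, fit = NULL,
                null_fit = NULL, flag = "monomorphic"))
  fit0 <- fit_vc(y, X0, kernels = list(polygenic = pk$kernel),
                 blocks = pk$blocks)
  X1 <- cbind(if (is.null(X0)) NULL else as.matrix(X0), snp = g)
  fit1 <- fit_vc(y, X1, kernels = list(polygenic = pk$kernel),
                 blocks = pk$blocks)
  stat <- max(0, 2 * (fit1$loglik - fit0$loglik))
  list(pvalue = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       effect = unname(fit1$fixef["snp"]),
       fit = fit1, null_fit = fit0, flag = "ok")
}

#' Linkage LOD before and after adjusting for a variant
#'
#' Recomputes the variance-components linkage LOD at a locus with and
#' without the candidate variant as a fixed covariate; a collapse of the
#' adjusted LOD toward zero indicates the variant explains the linkage
#' signal.
#'
#' @inheritParams measured_genotype_test
#' @param ibd locus IBD matrix Pi over the tested individuals (dimnames =
#'   ids), e.g. from [true_ibd_matrix()].
#' @return named numeric vector `c(unadjusted, adjusted)`.
#' @export
adjusted_lod <- function(trait, covariates, genotype, ibd, peds) {
  pk <- polygenic_kernel(peds)
  y <- trait[pk$ids]
  g <- genotype[pk$ids]
  Pi <- ibd[pk$ids, pk$ids]
  X0 <- if (!is.null(covariates) && NCOL(covariates) > 0)
    as.data.frame(covariates)[pk$ids, , drop = FALSE] else NULL
  lod_at <- function(X) {
    full <- fit_vc(y, X, kernels = list(polygenic = pk$kernel, locus = Pi),
                   blocks = pk$blocks)
    null <- fit_vc(y, X, kernels = list(polygenic = pk$kernel),
                   blocks = pk$blocks)
    lod_score(full, null)
  }
  lod_u <- lod_at(X0)
  if (stats::var(g) == 0) {
    lod_a <- lod_u  # constant genotype carries no information
  } else {
    X1 <- cbind(if (is.null(X0)) NULL else as.matrix(X0), snp = g)
    lod_a <- lod_at(X1)
  }
  c(unadjusted = lod_u, adjusted = lod_a)
}

#' Percent of trait variance attributed to a variant
#'
#' `100 * b^2 * var(genotype) / var(trait)` with `b` the fitted allele
#' substitution effect and empirical variances within the tested scope
#' (total-phenotypic-variance convention), capped at 100.
#'
#' @param effect fitted SNP effect.
#' @param genotype 0/1/2 vector in scope.
#' @param trait trait values in scope.
#' @return percent in \[0, 100\].
#' @export
variance_due_to_snp <- function(effect, genotype, trait) {
  vy <- stats::var(trait)
  if (!is.finite(vy) || vy == 0) stop("trait has zero variance")
  if (is.na(effect)) return(NA_real_)
  min(100, 100 * effect^2 * stats::var(genotype) / vy)
}

#' Bonferroni-significant variants
#'
#' @param pvalues named vector of association p-values.
#' @param m total number of tests performed (at least `length(pvalues)`).
#' @param alpha family-wise error rate (default 0.05).
#' @return names of variants with `p < alpha / m`.
#' @export
bonferroni_significant <- function(pvalues, m, alpha = 0.05) {
  if (m == 0) stop("number of tests m must be positive")
  if (m < sum(!is.na(pvalues)))
    stop("m must be at least the number of variants tested")
  if (!length(pvalues)) return(character(0))
  names(pvalues)[!is.na(pvalues) & pvalues < alpha / m]
}

#' Carrier overlap between two variants
#'
#' @param genotype_a,genotype_b aligned 0/1/2 vectors.
#' @return list `n_a`, `n_b`, `n_both` (carrier counts and intersection).
#' @export
carrier_overlap <- function(genotype_a, genotype_b) {
  stopifnot(length(genotype_a) == length(genotype_b))
  ca <- genotype_a >= 1L; cb <- genotype_b >= 1L
  list(n_a = sum(ca), n_b = sum(cb), n_both = sum(ca & cb))
}

#' Conditional association test
#'
#' Tests variant a with variant b included as an additional fixed
#' covariate, to disentangle associations at co-carried variant pairs.
#' A constant adjusting genotype reduces exactly to the unconditional
#' test; identical genotype vectors are collinear and flagged.
#'
#' @inheritParams measured_genotype_test
#' @param genotype_a variant under test.
#' @param adjust_for genotype vector controlled for.
#' @return as [measured_genotype_test()], with `flag = "collinear"` and no
#'   p-value when the two genotypes are identical.
#' @export
conditional_test <- function(trait, covariates, genotype_a, adjust_for,
                             peds) {
  ids <- names(genotype_a)
  if (identical(unname(genotype_a[ids]), unname(adjust_for[ids])))
    return(list(pvalue = NA_real_, effect = NA_real_, fit = NULL,
                null_fit = NULL, flag = "collinear"))
  covariates <- if (stats::var(adjust_for[ids]) == 0) covariates else {
    base <- if (!is.null(covariates) && NCOL(covariates) > 0)
      as.data.frame(covariates)[ids, , drop = FALSE]
    else data.frame(row.names = ids)
    base$snp_adj <- as.numeric(adjust_for[ids])
    base
  }
  measured_genotype_test(trait, covariates, genotype_a, peds)
}

#' Association of a candidate variant across family scopes
#'
#' Evaluates a candidate in the prioritized family, in the remaining
#' families (`"others"`) and in all families combined: association
#' p-value, copies and entering-founder counts, linkage LOD at the
#' variant's gene before/after adjusting for the variant, and the percent
#' of trait variance attributed to it.  Monomorphic scopes (e.g. zero
#' copies outside the family) report `NA` statistics.
#'
#' @param variant_id variant identifier in `study$variants`.
#' @param study a `sim_study`.
#' @param trait trait column name in `study$pheno`.
#' @param prioritized_family family id the candidate was discovered in.
#' @param covariates character vector of retained covariate columns.
#' @param gene gene whose locus IBD is used for the LOD attribution;
#'   defaults to the variant's own gene context.
#' @return data frame with rows for scopes `family`, `others`, `all`:
#'   `variant_id`, `scope`, `n`, `n_copies`, `n_founder_entries`,
#'   `pvalue`, `effect`, `lod_unadjusted`, `lod_adjusted`,
#'   `pct_variance_snp`.
#' @export
cross_family_replication <- function(variant_id, study, trait,
                                     prioritized_family,
                                     covariates = character(0),
                                     gene = NULL) {
  vrow <- match(variant_id, study$variants$id)
  if (is.na(vrow)) stop("unknown variant id: ", variant_id)
  if (is.null(gene)) gene <- study$variants$gene[vrow]
  g_all <- study$genotypes[, variant_id]
  lab <- study$descent[[gene]]
  scopes <- list(family = prioritized_family, others = "others", all = "all")
  rows <- lapply(names(scopes), function(sc) {
    peds <- scope_peds(study, scopes[[sc]], exclude = prioritized_family)
    ids <- unlist(lapply(peds, `[[`, "id"), use.names = FALSE)
    y <- stats::setNames(study$pheno[match(ids, study$pheno$id), trait], ids)
    X <- if (length(covariates))
      study$pheno[match(ids, study$pheno$id), covariates, drop = FALSE]
    else NULL
    g <- g_all[ids]
    copies <- sum(g)
    nfe <- sum(vapply(peds, function(p)
      founder_entry_count(p, g_all), integer(1)))
    mt <- measured_genotype_test(y, X, g, peds)
    if (mt$flag == "monomorphic") {
      lods <- c(unadjusted = NA_real_, adjusted = NA_real_)
      pct <- NA_real_
    } else {
      lods <- if (!is.null(lab))
        adjusted_lod(y, X, g, true_ibd_matrix(lab), peds)
      else c(unadjusted = NA_real_, adjusted = NA_real_)
      pct <- variance_due_to_snp(mt$effect, g, y)
    }
    data.frame(variant_id = variant_id, scope = sc, n = length(ids),
               n_copies = copies, n_founder_entries = nfe,
               pvalue = mt$pvalue, effect = mt$effect,
               lod_unadjusted = unname(lods["unadjusted"]),
               lod_adjusted = unname(lods["adjusted"]),
               pct_variance_snp = pct,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
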