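#' Fit a variance-components model by maximum likelihood
#'
#' Fits the multivariate-normal model `y = X b + g + e` where the random
#' effects have covariance `Omega = sum_m sigma2_m K_m + sigma2_e I` for a
#' set of positive semidefinite kernels `K_m` (typically the additive
#' kernel 2*Phi from [kinship_matrix()] and a locus-specific IBD kernel
#' Pi).  Fixed effects are profiled out by generalized least squares inside
#' the variance optimization; variances are optimized on the log scale from
#' a set of fixed deterministic starts, and every subset of kernels clamped
#' to zero is refit so boundary solutions are found exactly.  Families are
#' assumed independent, so `Omega` is block-diagonal over `blocks`.
#'
#' @param y numeric response vector.
#' @param covariates optional matrix/data frame of covariates, rows aligned
#'   with `y`; an intercept is always included.
#' @param kernels named list of square matrices aligned with `y`.
#' @param blocks factor assigning individuals to independent blocks
#'   (families); `NULL` for a single block.
#' @param n_restarts number of deterministic optimizer restarts.
#' @return object of class `vc_fit`: `fixef`, `se_fixef`, `vcov_fixef`,
#'   `sigma2` (one entry per kernel plus `"residual"`), `loglik`,
#'   `converged`, `n`, `kernel_names`.
#' @export
fit_vc <- function(y, covariates = NULL, kernels = list(), blocks = NULL,
                   n_restarts = 3) {
  y <- as.numeric(y)
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    cv <- as.matrix(as.data.frame(covariates))
    storage.mode(cv) <- "double"
    if (nrow(cv) != n) stop("covariates not aligned with trait")
    X <- cbind(X, cv)
  }
  if (anyNA(y) || anyNA(X)) stop("missing values in trait or covariates")
  m <- length(kernels)
  if (m > 0 && (is.null(names(kernels)) || any(names(kernels) == "")))
    stop("kernels must be named")
  for (K in kernels)
    if (!is.matrix(K) || nrow(K) != n || ncol(K) != n)
      stop("each kernel must be an n x n matrix aligned with the trait")
  if (is.null(blocks)) blocks <- factor(rep(1L, n))
  blocks <- as.factor(blocks)
  idx <- split(seq_len(n), blocks, drop = TRUE)

  Xb <- lapply(idx, function(i) X[i, , drop = FALSE])
  yb <- lapply(idx, function(i) y[i])
  Kb <- lapply(kernels, function(K) lapply(idx, function(i) K[i, i, drop = FALSE]))

  p <- ncol(X)
  eval_fit <- function(s2) {
    # s2: length m + 1, kernels then residual
    logdet <- 0
    XtOX <- matrix(0, p, p); XtOy <- numeric(p); ytOy <- 0
    for (b in seq_along(idx)) {
      nb <- length(yb[[b]])
      Om <- diag(s2[m + 1], nb)
      if (m > 0) for (j in seq_len(m)) Om <- Om + s2[j] * Kb[[j]][[b]]
      ch <- tryCatch(chol(Om), error = function(e) NULL)
      if (is.null(ch)) return(NULL)
      logdet <- logdet + 2 * sum(log(diag(ch)))
      Xi <- backsolve(ch, Xb[[b]], transpose = TRUE)
      yi <- backsolve(ch, yb[[b]], transpose = TRUE)
      XtOX <- XtOX + crossprod(Xi)
      XtOy <- XtOy + crossprod(Xi, yi)
      ytOy <- ytOy + sum(yi^2)
    }
    beta <- tryCatch(solve(XtOX, XtOy), error = function(e) NULL)
    if (is.null(beta)) return(NULL)
    quad <- ytOy - sum(beta * XtOy)
    list(loglik = -0.5 * (n * log(2 * pi) + logdet + quad),
         beta = drop(beta), XtOX = XtOX)
  }

  ols <- stats::lm.fit(X, y)
  v0 <- max(sum(ols$residuals^2) / n, 1e-8)
  jitter <- c(1, 0.2, 5, 0.05)[seq_len(max(1, n_restarts + 1))]

  best <- NULL
  free_sets <- list(seq_len(m))  # indices of kernels left free
  if (m > 0)
    for (drop_n in seq_len(m))
      free_sets <- c(free_sets,
                     utils::combn(m, m - drop_n, simplify = FALSE))
  for (free in unique(free_sets)) {
    nf <- length(free)
    make_s2 <- function(par) {
      s2 <- numeric(m + 1)
      if (nf > 0) s2[free] <- exp(par[seq_len(nf)])
      s2[m + 1] <- exp(par[nf + 1])
      s2
    }
    obj <- function(par) {
      f <- eval_fit(make_s2(par))
      if (is.null(f) || !is.finite(f$loglik)) return(1e10)
      -f$loglik
    }
    # restarts matter for the full model; boundary refits are easier
    starts <- if (nf == m) jitter else jitter[1]
    for (jf in starts) {
      par0 <- log(rep(v0 * jf / (nf + 1), nf + 1))
      opt <- tryCatch(
        stats::optim(par0, obj, method = "L-BFGS-B",
                     lower = log(v0) - 25, upper = log(v0) + 25,
                     control = list(maxit = 500)),
        error = function(e) NULL)
      if (is.null(opt)) next
      cand <- list(value = -opt$value, par = make_s2(opt$par),
                   conv = opt$convergence == 0)
      if (is.null(best) || cand$value > best$value + 1e-9) best <- cand
    }
  }
  if (is.null(best)) stop("variance-components optimization failed")

  f <- eval_fit(best$par)
  vcov_b <- tryCatch(solve(f$XtOX), error = function(e) matrix(NA, p, p))
  fixef <- stats::setNames(f$beta, colnames(X))
  se <- stats::setNames(sqrt(pmax(diag(vcov_b), 0)), colnames(X))
  s2 <- stats::setNames(best$par, c(names(kernels), "residual"))
  structure(list(fixef = fixef, se_fixef = se, vcov_fixef = vcov_b,
                 sigma2 = s2, loglik = f$loglik, converged = best$conv,
                 n = n, kernel_names = names(kernels)),
            class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("Variance-components fit (n = %d), loglik = %.3f%s\n", x$n,
              x$loglik, if (x$converged) "" else " [not converged]"))
  cat("  variance components:\n")
  for (nm in names(x$sigma2))
    cat(sprintf("    %-10s %.4g\n", nm, x$sigma2[nm]))
  invisible(x)
}

#' LOD score from nested variance-components fits
#'
#' The linkage LOD is the log10 likelihood ratio of the model with the
#' locus-specific variance component against the same model with that
#' component constrained to zero, floored at 0.
#'
#' @param full `vc_fit` including the locus kernel.
#' @param null `vc_fit` of the same data and fixed effects without it.
#' @return LOD score (>= 0).
#' @export
lod_score <- function(full, null) {
  stopifnot(inherits(full, "vc_fit"), inherits(null, "vc_fit"))
  if (full$n != null$n || !identical(names(full$fixef), names(null$fixef)))
    stop("mismatched scopes: full and null fits use different data or fixed effects")
  max(0, (full$loglik - null$loglik) / log(10))
}

#' Pointwise p-value of a LOD score
#'
#' Because the locus variance is constrained to be non-negative, the null
#' distribution of `2 ln(10) LOD` is the boundary mixture
#' 1/2 chi-square(0) : 1/2 chi-square(1); hence
#' `p = 0.5 * P(chisq_1 > 2 ln(10) lod)` for positive LOD and `p = 1` at
#' `lod = 0`.  Under this convention a LOD of 0.60 corresponds to a
#' pointwise p-value of 0.05 (to 2 decimals).
#'
#' @param lod LOD score(s), non-negative.
#' @return pointwise p-value(s) in (0, 1].
#' @examples
#' lod_to_pvalue(0.60)
#' @export
lod_to_pvalue <- function(lod) {
  if (any(lod < 0)) stop("LOD scores must be non-negative")
  ifelse(lod == 0, 1,
         0.5 * stats::pchisq(2 * log(10) * lod, df = 1, lower.tail = FALSE))
}

# block-diagonal additive kernel 2*Phi over a list of pedigrees, in the
# concatenated id order; returns kernel, blocks factor and ids
polygenic_kernel <- function(peds) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  ids <- unlist(lapply(peds, `[[`, "id"), use.names = FALSE)
  n <- length(ids)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  fam <- character(n)
  at <- 0L
  for (ped in peds) {
    take <- at + seq_len(nrow(ped))
    K[take, take] <- 2 * kinship_matrix(ped)
    fam[take] <- ped$family[1]
    at <- at + nrow(ped)
  }
  list(kernel = K, blocks = factor(fam, levels = unique(fam)), ids = ids)
}

#' Screen covariates in the polygenic model
#'
#' Fits the polygenic-only variance-components model with all candidate
#' covariates and retains those declared significant predictors at
#' `p < alpha` by a Wald test.
#'
#' @param trait named numeric vector of trait values.
#' @param covariates data frame/matrix of covariates with row names equal
#'   to the individual ids.
#' @param peds a [pedigree] or list of pedigrees.
#' @param alpha retention threshold on the Wald p-value (default 0.10).
#' @return character vector of retained covariate names (possibly empty).
#' @export
screen_covariates <- function(trait, covariates, peds, alpha = 0.10) {
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) == 0L) return(character(0))
  pk <- polygenic_kernel(peds)
  y <- trait[pk$ids]
  X <- covariates[pk$ids, , drop = FALSE]
  fit <- fit_vc(y, X, kernels = list(polygenic = pk$kernel),
                blocks = pk$blocks)
  b <- fit$fixef[colnames(X)]
  se <- fit$se_fixef[colnames(X)]
  pw <- 2 * stats::pnorm(-abs(b / se))
  names(pw)[!is.na(pw) & pw < alpha]
}

#' Variance-components linkage scan over gene positions
#'
#' Tests each gene with fully informative identity-by-descent sharing for
#' linkage with the trait: the locus-specific IBD matrix Pi at the gene
#' position enters as a second variance component next to the polygenic
#' kernel, and the LOD is the log10 likelihood ratio against the no-locus
#' model.  `scope` restricts the analysis to one family or uses all
#' families (block-diagonal covariance).
#'
#' @param study a `sim_study` (see [simulate_study()]) or compatible list
#'   with `pedigrees`, `pheno` and per-gene descent labels in `descent`.
#' @param trait name of the trait column in `study$pheno`.
#' @param scope family id, or `"all"`.
#' @param covariates character vector of covariate columns to keep as fixed
#'   effects (the retained set from [screen_covariates()]).
#' @param gene_map data frame with columns `gene`, `chrom`, `pos`; defaults
#'   to the study's own map.
#' @return data frame with one row per gene: `gene`, `chrom`, `pos`,
#'   `scope`, `lod`, `pvalue`, sorted by chromosome and position.
#' @export
scan_genes <- function(study, trait, scope = "all",
                       covariates = character(0), gene_map = study$gene_map) {
  peds <- scope_peds(study, scope)
  pk <- polygenic_kernel(peds)
  y <- study$pheno[match(pk$ids, study$pheno$id), trait]
  names(y) <- pk$ids
  X <- if (length(covariates))
    study$pheno[match(pk$ids, study$pheno$id), covariates, drop = FALSE]
  else NULL
  null_fit <- fit_vc(y, X, kernels = list(polygenic = pk$kernel),
                     blocks = pk$blocks)
  if (nrow(gene_map) == 0L)
    return(data.frame(gene = character(0), chrom = character(0),
                      pos = integer(0), scope = character(0),
                      lod = numeric(0), pvalue = numeric(0)))
  rows <- lapply(seq_len(nrow(gene_map)), function(i) {
    g <- gene_map$gene[i]
    lab <- study$descent[[g]]
    if (is.null(lab)) {
      warning("no descent labels for gene ", g, "; skipped")
      return(NULL)
    }
    Pi <- true_ibd_matrix(lab[pk$ids, , drop = FALSE])
    full <- fit_vc(y, X, kernels = list(polygenic = pk$kernel, locus = Pi),
                   blocks = pk$blocks)
    lod <- lod_score(full, null_fit)
    data.frame(gene = g, chrom = gene_map$chrom[i], pos = gene_map$pos[i],
               scope = scope, lod = lod, pvalue = lod_to_pvalue(lod),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(0), chrom = character(0),
                      pos = integer(0), scope = character(0),
                      lod = numeric(0), pvalue = numeric(0))
  out[order(out$chrom, out$pos), , drop = FALSE]
}

# pedigrees for a scope: one family id, "others" relative to `exclude`,
# or "all"
scope_peds <- function(study, scope, exclude = NULL) {
  if (identical(scope, "all")) return(study$pedigrees)
  if (identical(scope, "others")) {
    if (is.null(exclude)) stop("scope 'others' needs the excluded family")
    return(study$pedigrees[setdiff(names(study$pedigrees), exclude)])
  }
  if (!scope %in% names(study$pedigrees))
    stop("unknown family id: ", scope)
  study$pedigrees[scope]
}
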