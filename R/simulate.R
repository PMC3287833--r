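#' Configuration for a synthetic extended-family study
#'
#' Defines the conditions of a simulated study: a set of multi-generation
#' extended families, family-private and shared rare variants gene-dropped
#' from founders, Sex/Age/Smoking covariates, and quantitative traits
#' generated under the oligogenic linear model (mean + covariate effects +
#' additive/dominance QTL contributions + normal residuals).  The default
#' scenario mirrors an eight-family exome study in which one family
#' ("family 7") privately carries two large-effect rare variants for the
#' first trait and one for the second, while the remaining families see
#' only shared background variation.
#'
#' @param n_families number of families.
#' @param family_size_range inclusive range of family sizes (members).
#' @param n_generations generations per family.
#' @param seeded_family id of the family carrying the private functional
#'   variants in the default `qtl_specs`.
#' @param traits trait names to simulate.
#' @param covariate_effects named list (per trait) of effect sizes, in
#'   trait units per covariate unit, for `Sex` (0/1), `Age` (years) and
#'   `Smoking` (0/1).
#' @param qtl_specs data frame describing functional variants: columns
#'   `trait`, `family` (a family id or `"shared"`), `n_founders` (1 or 2
#'   entering founders for private variants), `a` (additive effect), `d`
#'   (dominance effect), `freq` (founder-allele frequency, shared variants
#'   only).  `NULL` for the default scenario.
#' @param n_null_variants number of nonfunctional rare variants.
#' @param min_copies_functional private functional variants are dropped so
#'   that at least this many copies segregate in the target family
#'   (entering founder chosen accordingly), emulating rare alleles that
#'   entered the family enough generations ago to have spread.
#' @param residual_sd residual standard deviation, trait units.
#' @param mu overall trait mean.
#' @param gene_map data frame `gene`, `chrom`, `pos` (1-based bp); `NULL`
#'   for the default map of 48 genes on 3 chromosomes.
#' @param mean_children mean sibship size.
#' @param marry_prob probability a non-final-generation child marries (the
#'   spouse enters as a new founder).
#' @param smoking_prob marginal smoking probability.
#' @param age_confounding if `TRUE`, smoking probability increases with
#'   age, giving the covariate screen a confounded case.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_families = 8,
                       family_size_range = c(73, 128),
                       n_generations = 5,
                       seeded_family = "7",
                       traits = c("Q1", "Q2"),
                       covariate_effects = NULL,
                       qtl_specs = NULL,
                       n_null_variants = 60,
                       min_copies_functional = 20,
                       residual_sd = 1,
                       mu = 0,
                       gene_map = NULL,
                       mean_children = 3,
                       marry_prob = 0.7,
                       smoking_prob = 0.3,
                       age_confounding = FALSE) {
  stopifnot(length(family_size_range) == 2,
            family_size_range[1] >= 3, family_size_range[2] <= 500,
            family_size_range[1] <= family_size_range[2],
            residual_sd > 0, n_generations >= 2, n_families >= 1)
  seeded_family <- as.character(seeded_family)
  if (is.null(covariate_effects)) {
    covariate_effects <- stats::setNames(rep(list(NULL), length(traits)), traits)
    defaults <- list(c(Sex = 0.25, Age = 0.028, Smoking = 0.60),
                     c(Sex = 0.10, Age = 0.004, Smoking = 0.15))
    for (i in seq_along(traits))
      covariate_effects[[i]] <- defaults[[min(i, length(defaults))]]
  }
  if (is.null(qtl_specs)) {
    qtl_specs <- data.frame(
      trait = c("Q1", "Q1", "Q1", "Q2", "Q2"),
      family = c(seeded_family, seeded_family, "shared",
                 seeded_family, "shared"),
      n_founders = c(1L, 1L, NA, 1L, NA),
      a = c(3.0, 2.0, 0.6, 1.2, 0.5),
      d = 0,
      freq = c(NA, NA, 0.012, NA, 0.012),
      stringsAsFactors = FALSE)
    qtl_specs <- qtl_specs[qtl_specs$trait %in% traits, , drop = FALSE]
  }
  if (is.null(gene_map)) gene_map <- default_gene_map()
  stopifnot(all(gene_map$pos >= 1))
  structure(list(n_families = n_families,
                 family_size_range = family_size_range,
                 n_generations = n_generations,
                 seeded_family = seeded_family,
                 traits = traits,
                 covariate_effects = covariate_effects,
                 qtl_specs = qtl_specs,
                 n_null_variants = n_null_variants,
                 min_copies_functional = min_copies_functional,
                 residual_sd = residual_sd,
                 mu = mu,
                 gene_map = gene_map,
                 mean_children = mean_children,
                 marry_prob = marry_prob,
                 smoking_prob = smoking_prob,
                 age_confounding = age_confounding),
            class = "sim_config")
}

#' Default gene map: 48 genes spread over 3 chromosomes
#' @return data frame with `gene`, `chrom`, `pos`.
#' @export
default_gene_map <- function() {
  data.frame(gene = sprintf("G%02d", 1:48),
             chrom = as.character(rep(1:3, each = 16)),
             pos = rep(2e6 + (0:15) * 3e6, times = 3),
             stringsAsFactors = FALSE)
}

sample1 <- function(x) x[sample.int(length(x), 1L)]

#' Simulate one extended pedigree
#'
#' Grows a multi-generation family: founding couples at the top, sibships
#' of mean size `mean_children`, and spouses marrying in as new founders at
#' each non-final generation.  Realizations are retried (bounded) until the
#' family size falls in `family_size_range` and, for families of 30+
#' members, the founder fraction lies in 0.20-0.40.
#'
#' @param config a [sim_config()].
#' @param family_index integer or character family label.
#' @return a [pedigree] with a `generation` attribute (named integer
#'   vector).
#' @export
simulate_pedigree <- function(config, family_index) {
  fid <- as.character(family_index)
  rng_sizes <- config$family_size_range[1]:config$family_size_range[2]
  G <- config$n_generations
  # expected members per founding couple under the growth parameters
  exp_couple <- local({
    cp <- 1; tot <- 2
    for (g in seq_len(G - 1L) + 1L) {
      kids <- cp * config$mean_children
      sp <- if (g < G) kids * config$marry_prob else 0
      tot <- tot + kids + sp
      cp <- sp
    }
    tot
  })
  for (attempt in seq_len(200L)) {
    target <- sample1(rng_sizes)
    c0 <- max(1L, round(target / exp_couple))
    id <- character(0); father <- character(0); mother <- character(0)
    sex <- integer(0); gen <- integer(0)
    cnt <- 0L
    new_id <- function() {
      cnt <<- cnt + 1L
      sprintf("%s_%03d", fid, cnt)
    }
    add <- function(s, g, fa = NA_character_, mo = NA_character_) {
      i <- new_id()
      id <<- c(id, i); father <<- c(father, fa); mother <<- c(mother, mo)
      sex <<- c(sex, s); gen <<- c(gen, g)
      i
    }
    couples <- vector("list", c0)
    for (j in seq_len(c0))
      couples[[j]] <- c(add(1L, 1L), add(2L, 1L))
    ok <- TRUE
    for (g in seq_len(G - 1L) + 1L) {
      nxt <- list()
      for (cp in couples) {
        nk <- 1L + stats::rpois(1L, config$mean_children - 1)
        for (k in seq_len(nk)) {
          s <- sample1(1:2)
          child <- add(s, g, cp[1], cp[2])
          if (g < G && stats::runif(1) < config$marry_prob) {
            spouse <- add(if (s == 1L) 2L else 1L, g)
            nxt[[length(nxt) + 1L]] <-
              if (s == 1L) c(child, spouse) else c(spouse, child)
          }
        }
      }
      couples <- nxt
      if (g < G && !length(couples)) { ok <- FALSE; break }
    }
    if (!ok) next
    size <- length(id)
    if (size < config$family_size_range[1] ||
        size > config$family_size_range[2]) next
    frac <- sum(is.na(father)) / size
    if (size >= 30L && (frac < 0.20 || frac > 0.40)) next
    ped <- pedigree(fid, id, father, mother, sex)
    attr(ped, "generation") <- stats::setNames(gen, id)
    return(ped)
  }
  stop("could not generate a pedigree with the requested size after 200 attempts")
}

#' Gene-drop founder alleles through a pedigree
#'
#' Labels each founder's two alleles uniquely, makes each entering founder
#' heterozygous for the rare allele, and transmits one allele from each
#' parent, chosen independently with probability 1/2 (or following the
#' supplied segregation `indicators`, so several variants can share the
#' descent pattern of one locus).  The descent labels record the
#' originating founder allele of every transmitted allele, giving fully
#' informative identity by descent at the locus.
#'
#' @param ped a [pedigree].
#' @param entering_founders ids of founders carrying one copy of the rare
#'   allele.
#' @param indicators optional n x 2 matrix (values 1/2; rows named by id)
#'   giving the paternal/maternal allele choice for each non-founder.
#' @return list with `genotype` (named 0/1/2 vector), `descent` (n x 2
#'   integer label matrix), `indicators`, `rare_labels`, and
#'   `founder_labels` (2-column matrix of allele labels per founder).
#' @export
gene_drop <- function(ped, entering_founders = character(0),
                      indicators = NULL) {
  ped <- ensure_pedigree(ped)
  n <- nrow(ped)
  fnd <- founders(ped)
  entering_founders <- as.character(entering_founders)
  if (!all(entering_founders %in% fnd))
    stop("entering founder(s) not founders of the pedigree: ",
         paste(setdiff(entering_founders, fnd), collapse = ", "))
  fa <- match(ped$father, ped$id); mo <- match(ped$mother, ped$id)
  if (is.null(indicators)) {
    indicators <- matrix(sample(1:2, 2L * n, replace = TRUE), ncol = 2,
                         dimnames = list(ped$id, c("pat", "mat")))
    indicators[is.na(fa), ] <- NA_integer_
  } else {
    indicators <- indicators[ped$id, , drop = FALSE]
  }
  flab <- matrix(seq_len(2L * length(fnd)), ncol = 2, byrow = TRUE,
                 dimnames = list(fnd, NULL))
  desc <- matrix(NA_integer_, n, 2, dimnames = list(ped$id, NULL))
  desc[fnd, ] <- flab
  for (i in attr(ped, "topo")) {
    if (!is.na(fa[i])) {
      desc[i, 1] <- desc[fa[i], indicators[i, 1]]
      desc[i, 2] <- desc[mo[i], indicators[i, 2]]
    }
  }
  rare_labels <- if (length(entering_founders))
    flab[cbind(match(entering_founders, fnd),
               sample(1:2, length(entering_founders), replace = TRUE))]
  else integer(0)
  genotype <- geno_from_descent(desc, rare_labels)
  list(genotype = genotype, descent = desc, indicators = indicators,
       rare_labels = rare_labels, founder_labels = flab)
}

# allele-copy count per individual given descent labels and the set of
# founder-allele labels carrying the rare allele
geno_from_descent <- function(desc, rare_labels) {
  g <- (desc[, 1] %in% rare_labels) + (desc[, 2] %in% rare_labels)
  stats::setNames(as.integer(g), rownames(desc))
}

#' Realized IBD sharing matrix from descent labels
#'
#' `Pi(i, j)` is the number of allele pairs shared identical by descent
#' between i and j, divided by 2 -- 0, 0.5 or 1 for non-inbred pairs.  The
#' expectation of `Pi(i, j)` over repeated gene drops equals twice the
#' kinship coefficient.
#'
#' @param descent n x 2 integer matrix of founder-allele labels (rows named
#'   by individual id), e.g. from [gene_drop()].
#' @return symmetric n x n matrix.
#' @export
true_ibd_matrix <- function(descent) {
  a1 <- descent[, 1]; a2 <- descent[, 2]
  Pi <- (outer(a1, a1, "==") + outer(a1, a2, "==") +
         outer(a2, a1, "==") + outer(a2, a2, "==")) / 2
  dimnames(Pi) <- list(rownames(descent), rownames(descent))
  Pi
}

#' Simulate a complete family study
#'
#' Generates pedigrees, per-gene descent patterns (fully informative IBD),
#' rare variants (functional per `qtl_specs`, plus nonfunctional null
#' variants), Sex/Age/Smoking covariates and quantitative traits under the
#' oligogenic linear model, together with a truth record for recovery
#' tests.  All randomness derives from `seed` through fixed per-stage
#' offsets, so the study is fully reproducible.
#'
#' @param config a [sim_config()].
#' @param seed integer master seed.
#' @return object of class `sim_study`: list with `pedigrees`, `pheno`
#'   (id, family, Sex, Age, Smoking and one column per trait),
#'   `genotypes` (individuals x variants 0/1/2 matrix), `variants`
#'   (id, chrom, pos, gene, type), `gene_map`, `descent` (per-gene label
#'   matrices), `truth`, `config`, `seed`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1L) {
  stage_seed <- function(k) as.integer((seed %% 100000L) * 10007L + k * 7919L)

  set.seed(stage_seed(1L))
  peds <- lapply(seq_len(config$n_families), function(i)
    simulate_pedigree(config, i))
  names(peds) <- as.character(seq_len(config$n_families))
  ids <- unlist(lapply(peds, `[[`, "id"), use.names = FALSE)
  fam_of <- rep(names(peds), vapply(peds, nrow, integer(1)))
  n <- length(ids)

  gene_map <- config$gene_map

  # per-gene descent: independent drop per family, labels offset so they
  # are unique study-wide; keep indicators so variants can share a locus
  set.seed(stage_seed(2L))
  offsets <- cumsum(c(0, head(2 * vapply(peds, function(p)
    length(founders(p)), integer(1)), -1)))
  names(offsets) <- names(peds)
  descent <- list(); gene_ind <- list()
  for (gi in seq_len(nrow(gene_map))) {
    g <- gene_map$gene[gi]
    dm <- matrix(NA_integer_, n, 2, dimnames = list(ids, NULL))
    gene_ind[[g]] <- list()
    for (f in names(peds)) {
      gd <- gene_drop(peds[[f]])
      dm[rownames(gd$descent), ] <- gd$descent + offsets[[f]]
      gene_ind[[g]][[f]] <- gd$indicators
    }
    descent[[g]] <- dm
  }

  # founder-allele labels per family (offset to the study-wide labels)
  flabs <- lapply(names(peds), function(f) {
    fnd <- founders(peds[[f]])
    matrix(seq_len(2L * length(fnd)) + offsets[[f]], ncol = 2, byrow = TRUE,
           dimnames = list(fnd, NULL))
  })
  names(flabs) <- names(peds)

  set.seed(stage_seed(3L))
  specs <- config$qtl_specs
  n_spec <- if (is.null(specs)) 0L else nrow(specs)
  spec_genes <- if (n_spec > 0)
    gene_map$gene[unique(pmax(1, round(seq(0.15, 0.85, length.out = n_spec) *
                                        nrow(gene_map))))]
  else character(0)
  variants <- list(); geno_cols <- list(); truth_fun <- list()
  vc_counter <- stats::setNames(rep(0L, length(unique(gene_map$chrom))),
                                unique(gene_map$chrom))
  add_variant <- function(gene, g_vec, type, trait = NA, a = NA, d = NA,
                          families_entered = list()) {
    gi <- match(gene, gene_map$gene)
    chrom <- gene_map$chrom[gi]
    vc_counter[chrom] <<- vc_counter[chrom] + 1L
    vid <- sprintf("C%sS%d", chrom, vc_counter[chrom])
    pos <- gene_map$pos[gi] + sample1(seq(-3e5, 3e5, by = 1e3))
    variants[[length(variants) + 1L]] <<-
      data.frame(id = vid, chrom = chrom, pos = pos, gene = gene,
                 type = type, stringsAsFactors = FALSE)
    geno_cols[[length(geno_cols) + 1L]] <<- stats::setNames(list(g_vec), vid)
    if (type == "functional")
      truth_fun[[length(truth_fun) + 1L]] <<-
        data.frame(variant = vid, trait = trait, gene = gene,
                   a = a, d = d,
                   families = paste(names(families_entered), collapse = ","),
                   entering_founders = paste(unlist(families_entered),
                                             collapse = ","),
                   stringsAsFactors = FALSE)
    vid
  }

  drop_private <- function(gene, fam, n_founders, min_copies) {
    ped <- peds[[fam]]
    fl <- flabs[[fam]]
    # a private functional variant must have spread through the family:
    # redraw the locus segregation pattern (bounded) until some founder
    # allele reaches the copy floor
    if (min_copies > 0L && n_founders == 1L) {
      for (try in seq_len(40L)) {
        dm_try <- descent[[gene]][ped$id, , drop = FALSE]
        if (max(tabulate(dm_try - offsets[[fam]],
                         nbins = 2L * length(founders(ped)))) >= min_copies)
          break
        gd <- gene_drop(peds[[fam]])
        descent[[gene]][rownames(gd$descent), ] <<- gd$descent + offsets[[fam]]
        gene_ind[[gene]][[fam]] <<- gd$indicators
      }
    }
    dm <- descent[[gene]][ped$id, , drop = FALSE]
    slots <- cbind(label = as.vector(t(fl)),
                   copies = vapply(as.vector(t(fl)), function(l)
                     sum(dm == l), integer(1)))
    if (n_founders == 1L) {
      okrows <- which(slots[, "copies"] >= min_copies)
      pick <- if (length(okrows)) sample1(okrows)
              else which.max(slots[, "copies"])
      labs <- slots[pick, "label"]
    } else {
      best <- NULL
      for (try in seq_len(60L)) {
        frows <- sample.int(nrow(fl), 2L)
        cand <- fl[cbind(frows, sample(1:2, 2L, replace = TRUE))]
        cp <- sum(dm %in% cand)
        if (is.null(best) || cp > best$cp) best <- list(labs = cand, cp = cp)
        if (cp >= min_copies) break
      }
      labs <- best$labs
    }
    g <- stats::setNames(integer(n), ids)
    g[ped$id] <- geno_from_descent(dm, labs)
    ent <- rownames(fl)[apply(fl, 1, function(r) any(r %in% labs))]
    list(g = g, entering = stats::setNames(list(ent), fam))
  }

  drop_shared <- function(gene, freq) {
    g <- stats::setNames(integer(n), ids)
    entering <- list()
    for (f in names(peds)) {
      fl <- flabs[[f]]
      hit <- which(stats::runif(length(fl)) < freq)
      if (!length(hit)) next
      labs <- as.vector(fl)[hit]
      dm <- descent[[gene]][peds[[f]]$id, , drop = FALSE]
      g[peds[[f]]$id] <- geno_from_descent(dm, labs)
      ent <- rownames(fl)[apply(fl, 1, function(r) any(r %in% labs))]
      if (length(ent)) entering[[f]] <- ent
    }
    list(g = g, entering = entering)
  }

  if (n_spec > 0) {
    for (i in seq_len(n_spec)) {
      sp <- specs[i, ]
      gene <- spec_genes[min(i, length(spec_genes))]
      if (identical(sp$family, "shared")) {
        dr <- drop_shared(gene, sp$freq)
      } else {
        dr <- drop_private(gene, as.character(sp$family), sp$n_founders,
                           config$min_copies_functional)
      }
      add_variant(gene, dr$g, "functional", trait = sp$trait,
                  a = sp$a, d = sp$d, families_entered = dr$entering)
    }
  }
  for (i in seq_len(config$n_null_variants)) {
    gene <- sample1(gene_map$gene)
    if (stats::runif(1) < 0.25) {
      dr <- drop_shared(gene, stats::runif(1, 0.01, 0.03))
    } else {
      fam <- sample1(names(peds))
      dr <- drop_private(gene, fam, sample1(1:2), 0L)
    }
    if (sum(dr$g) == 0L) next  # allele died out; unobservable
    add_variant(gene, dr$g, "null")
  }
  variants <- do.call(rbind, variants)
  genotypes <- do.call(cbind, lapply(geno_cols, `[[`, 1L))
  colnames(genotypes) <- variants$id
  rownames(genotypes) <- ids

  # covariates
  set.seed(stage_seed(4L))
  gen_all <- unlist(lapply(peds, function(p) attr(p, "generation")),
                    use.names = FALSE)
  sex_all <- unlist(lapply(peds, `[[`, "sex"), use.names = FALSE)
  G <- config$n_generations
  age <- 20 + (G - gen_all) * 16 + stats::runif(n, 0, 12)
  smoke_p <- if (config$age_confounding)
    stats::plogis(stats::qlogis(config$smoking_prob) + 0.04 * (age - 50))
  else rep(config$smoking_prob, n)
  pheno <- data.frame(id = ids, family = fam_of,
                      Sex = as.integer(sex_all == 2L),
                      Age = round(age, 1),
                      Smoking = stats::rbinom(n, 1L, smoke_p),
                      stringsAsFactors = FALSE)
  rownames(pheno) <- ids

  study <- structure(list(config = config, seed = seed, pedigrees = peds,
                          pheno = pheno, genotypes = genotypes,
                          variants = variants, gene_map = gene_map,
                          descent = descent, gene_indicators = gene_ind,
                          truth = NULL),
                     class = "sim_study")

  set.seed(stage_seed(5L))
  tr <- simulate_traits(study)
  study$pheno <- cbind(study$pheno, as.data.frame(tr))

  fun_df <- if (length(truth_fun)) do.call(rbind, truth_fun) else
    data.frame(variant = character(0), trait = character(0),
               gene = character(0), a = numeric(0), d = numeric(0),
               families = character(0), entering_founders = character(0))
  counts <- list()
  for (tn in config$traits) {
    vv <- fun_df$variant[fun_df$trait == tn]
    counts[[tn]] <- vapply(names(peds), function(f) {
      if (!length(vv)) return(0L)
      sum(colSums(genotypes[peds[[f]]$id, vv, drop = FALSE]) > 0L)
    }, integer(1))
  }
  study$truth <- list(functional = fun_df, true_qtl_counts = counts,
                      seeded_family = config$seeded_family)
  study
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("Simulated study: %d families, %d individuals, %d variants, %d genes\n",
              length(x$pedigrees), nrow(x$pheno), ncol(x$genotypes),
              nrow(x$gene_map)))
  cat("  traits:", paste(x$config$traits, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate trait values for a study
#'
#' Draws trait vectors under the generative model
#' `Y = mu + X beta + sum_i [a_i (g_i - 1) + d_i 1(g_i = 1)] + e`
#' with i.i.d. normal residuals, using the study's genotypes, covariates
#' and the functional-variant specification in its configuration.  Uses the
#' current RNG state.
#'
#' @param study a `sim_study` with populated genotypes and covariates.
#' @param config configuration; defaults to the study's own.
#' @return numeric matrix (individuals x traits).
#' @export
simulate_traits <- function(study, config = study$config) {
  if (is.null(study$genotypes)) stop("study has no genotypes")
  ids <- study$pheno$id
  n <- length(ids)
  out <- matrix(0, n, length(config$traits),
                dimnames = list(ids, config$traits))
  # map spec rows to the functional variant columns, in order
  fun_ids <- study$variants$id[study$variants$type == "functional"]
  specs <- config$qtl_specs
  for (j in seq_along(config$traits)) {
    tn <- config$traits[j]
    eff <- config$covariate_effects[[tn]]
    y <- rep(config$mu, n)
    for (cv in names(eff)) y <- y + eff[[cv]] * study$pheno[[cv]]
    if (!is.null(specs) && nrow(specs) > 0) {
      rows <- which(specs$trait == tn)
      for (r in rows) {
        vid <- fun_ids[r]
        g <- study$genotypes[ids, vid]
        y <- y + specs$a[r] * (g - 1) + specs$d[r] * (g == 1)
      }
    }
    out[, j] <- y + stats::rnorm(n, 0, config$residual_sd)
  }
  out
}

#' Write a simulated study to disk
#'
#' Emits plain-text files: PLINK PED (`study.ped`), VCF 4.2 with GT
#' (`variants.vcf`), covariates + traits (`phenotypes.tsv`), the gene map
#' (`gene_map.tsv`), per-gene descent labels (`descent.tsv`) and the truth
#' record (`truth.json`).
#'
#' @param study a `sim_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ped(study$pedigrees, file.path(dir, "study.ped"))
  write_vcf(study$genotypes, study$variants, file.path(dir, "variants.vcf"))
  utils::write.table(study$pheno, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$gene_map, file.path(dir, "gene_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dl <- do.call(rbind, lapply(names(study$descent), function(g) {
    d <- study$descent[[g]]
    data.frame(gene = g, id = rownames(d), allele1 = d[, 1], allele2 = d[, 2],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(dl, file.path(dir, "descent.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

# minimal VCF 4.2 writer (GT only); genotypes: individuals x variants
write_vcf <- function(genotypes, variants, path) {
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  gt <- t(genotypes[, variants$id, drop = FALSE])
  codes <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(genotypes)), collapse = "\t"))
  body <- vapply(seq_len(nrow(variants)), function(i) {
    paste(c(variants$chrom[i], variants$pos[i], variants$id[i], "A", "T",
            ".", "PASS", ".", "GT", codes[gt[i, ] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a study back from disk
#'
#' Inverse of [write_study()]; the VCF is parsed with `vcfR`.
#'
#' @param dir directory written by [write_study()].
#' @return a `sim_study`-compatible list (without the generating config).
#' @export
read_study <- function(dir) {
  peds <- read_ped(file.path(dir, "study.ped"))
  pheno <- utils::read.table(file.path(dir, "phenotypes.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE,
                             colClasses = c(id = "character",
                                            family = "character"))
  rownames(pheno) <- pheno$id
  gene_map <- utils::read.table(file.path(dir, "gene_map.tsv"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE,
                                colClasses = c(chrom = "character"))
  v <- vcfR::read.vcfR(file.path(dir, "variants.vcf"), verbose = FALSE)
  gtchar <- vcfR::extract.gt(v)
  geno <- matrix(match(gtchar, c("0/0", "0/1", "1/1")) - 1L,
                 nrow = nrow(gtchar), dimnames = dimnames(gtchar))
  variants <- data.frame(id = vcfR::getID(v),
                         chrom = as.character(vcfR::getCHROM(v)),
                         pos = vcfR::getPOS(v), stringsAsFactors = FALSE)
  dl <- utils::read.table(file.path(dir, "descent.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(id = "character"))
  descent <- lapply(split(dl, dl$gene), function(d) {
    m <- cbind(d$allele1, d$allele2)
    rownames(m) <- d$id
    m[pheno$id[pheno$id %in% d$id], , drop = FALSE]
  })
  truth <- tryCatch(jsonlite::read_json(file.path(dir, "truth.json"),
                                        simplifyVector = TRUE),
                    error = function(e) NULL)
  structure(list(pedigrees = peds, pheno = pheno,
                 genotypes = t(geno)[pheno$id, , drop = FALSE],
                 variants = variants, gene_map = gene_map,
                 descent = descent, truth = truth),
            class = "sim_study")
}
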