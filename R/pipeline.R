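#' Pipeline configuration
#'
#' Bundles every threshold and setting of the full analysis: simulate (or
#' load) a study, run the joint and per-family oligogenic segregation
#' analyses, prioritize families with excess QTLs, scan prioritized
#' families for linkage, filter rare variants in linked regions, and test
#' candidates by measured-genotype association with Bonferroni correction
#' over the candidates actually tested.
#'
#' @param sim a [sim_config()] describing the study to simulate, or `NULL`
#'   when `input_dir` is given.
#' @param input_dir directory written by [write_study()], or `NULL`.
#' @param seed master seed for every stage.
#' @param seg_settings settings for [run_segregation()].
#' @param covariates covariate columns offered to the model.
#' @param prioritize_threshold minimum excess QTL count (default 1.0).
#' @param lod_threshold LOD defining linked regions (default 0.60).
#' @param window_bp linked-region window width (default 1e6).
#' @param max_founders,min_copies,maf_max candidate filters (defaults 2,
#'   5, 0.05).
#' @param alpha family-wise error rate for the Bonferroni step.
#' @param compute_table1 whether to run the joint (all-families)
#'   segregation analysis for the variance-partition table.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL, seed = 1L,
                            seg_settings = famqtl::seg_settings(),
                            covariates = c("Sex", "Age", "Smoking"),
                            prioritize_threshold = 1.0,
                            lod_threshold = 0.60, window_bp = 1e6,
                            max_founders = 2L, min_copies = 5L,
                            maf_max = 0.05, alpha = 0.05,
                            compute_table1 = TRUE) {
  if (is.null(sim) == is.null(input_dir))
    stop("exactly one of `sim` and `input_dir` must be given")
  stopifnot(prioritize_threshold > 0, lod_threshold > 0, window_bp > 0,
            max_founders >= 0, min_copies >= 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar settings are read from the named YAML fields; the `sim` block,
#' if present, is passed to [sim_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim)
         else if (is.null(y$input_dir)) sim_config() else NULL
  seg <- if (!is.null(y$seg_settings)) do.call(seg_settings, y$seg_settings)
         else seg_settings()
  args <- y[intersect(names(y),
                      c("input_dir", "seed", "covariates",
                        "prioritize_threshold", "lod_threshold", "window_bp",
                        "max_founders", "min_copies", "maf_max", "alpha",
                        "compute_table1"))]
  do.call(pipeline_config,
          c(list(sim = sim, seg_settings = seg), args))
}

#' Run the full prioritization pipeline
#'
#' Executes simulate/load, segregation, family prioritization, linkage,
#' candidate filtering and association in order.  Traits for which no
#' family shows at least the configured excess QTL count are dropped from
#' the downstream stages.  A stage failure for one trait is recorded in
#' the report's error manifest without aborting the others.
#'
#' @param config a [pipeline_config()].
#' @return object of class `study_report`: `table1` (variance partitions),
#'   `table2` (per-family QTL counts with excess and prioritization),
#'   `table3` (association results of Bonferroni-significant candidates
#'   across scopes), `candidates`, `conditional`, `errors`, `meta`, and
#'   the underlying `study`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  study <- if (!is.null(config$sim))
    simulate_study(config$sim, seed = config$seed)
  else read_study(config$input_dir)
  traits <- intersect(config$sim$traits %||% colnames(study$pheno),
                      colnames(study$pheno))
  traits <- setdiff(traits, c("id", "family", config$covariates))
  peds <- study$pedigrees
  pheno <- study$pheno
  covs <- pheno[, config$covariates, drop = FALSE]
  rownames(covs) <- pheno$id

  table1 <- list(); table2 <- list(); table3 <- list()
  candidates <- list(); conditional <- list(); errors <- list()

  fam_sizes <- vapply(peds, nrow, integer(1))
  for (tn in traits) {
    res <- tryCatch({
      y <- stats::setNames(pheno[[tn]], pheno$id)

      if (isTRUE(config$compute_table1)) {
        set.seed(config$seed)
        joint <- run_segregation(y, covs, peds, config$seg_settings)
        vp <- variance_partition(joint)
        table1[[tn]] <- data.frame(
          trait = tn, t(round(vp$covariate_pct, 1)),
          qtl_pct = round(vp$qtl_pct, 1),
          expected_k = round(vp$expected_k, 1),
          residual_pct = round(vp$residual_pct, 1),
          heritability_pct = round(vp$heritability_pct, 1),
          stringsAsFactors = FALSE)
      }

      counts <- per_family_qtl_counts(y, covs, peds, config$seg_settings,
                                      seed = config$seed)
      excess <- vapply(names(counts), function(f) excess_qtls(counts, f),
                       numeric(1))
      pri <- prioritize_families(counts, config$prioritize_threshold)
      table2[[tn]] <- data.frame(
        trait = tn, family = names(counts),
        family_size = fam_sizes[names(counts)],
        expected_k = counts, excess = excess,
        prioritized = names(counts) %in% pri,
        stringsAsFactors = FALSE, row.names = NULL)

      if (!length(pri)) {
        message("trait ", tn, ": no family with excess QTLs >= ",
                config$prioritize_threshold, "; not analyzed further")
        next_trait <- NULL
      } else {
        retained <- screen_covariates(y, covs, peds)
        for (fam in pri) {
          scan <- scan_genes(study, tn, scope = fam, covariates = retained)
          regions <- linked_regions(scan, config$lod_threshold,
                                    config$window_bp)
          cands <- collect_candidates(regions, study, config$max_founders,
                                      config$min_copies, config$maf_max)
          if (!nrow(cands)) next
          cands$trait <- tn
          fam_ids <- peds[[fam]]$id
          yf <- y[fam_ids]
          Xf <- if (length(retained)) covs[fam_ids, retained, drop = FALSE]
                else NULL
          pv <- vapply(cands$variant_id, function(v) {
            mt <- measured_genotype_test(yf, Xf,
                                         study$genotypes[fam_ids, v],
                                         peds[fam])
            mt$pvalue
          }, numeric(1))
          cands$pvalue_family <- pv
          m <- nrow(cands)
          sig <- bonferroni_significant(stats::setNames(pv, cands$variant_id),
                                        m, config$alpha)
          cands$significant <- cands$variant_id %in% sig
          candidates[[paste(tn, fam)]] <- cands
          for (v in sig) {
            rep3 <- cross_family_replication(
              v, study, tn, fam, covariates = retained,
              gene = cands$gene_context[match(v, cands$variant_id)])
            rep3$trait <- tn
            rep3$n_tests <- m
            table3[[paste(tn, v)]] <- rep3
          }
          # conditional analysis for co-carried significant pairs
          if (length(sig) >= 2) {
            for (i in seq_len(length(sig) - 1)) for (j in (i + 1):length(sig)) {
              ga <- study$genotypes[fam_ids, sig[i]]
              gb <- study$genotypes[fam_ids, sig[j]]
              ov <- carrier_overlap(ga, gb)
              if (ov$n_both >= 0.5 * min(ov$n_a, ov$n_b) && ov$n_both > 0) {
                p_ab <- conditional_test(yf, Xf, ga, gb, peds[fam])$pvalue
                p_ba <- conditional_test(yf, Xf, gb, ga, peds[fam])$pvalue
                conditional[[paste(tn, sig[i], sig[j])]] <- data.frame(
                  trait = tn, variant_a = sig[i], variant_b = sig[j],
                  n_both = ov$n_both,
                  p_a_given_b = p_ab, p_b_given_a = p_ba,
                  stringsAsFactors = FALSE)
              }
            }
          }
        }
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) errors[[tn]] <- res
  }

  structure(list(
    table1 = if (length(table1)) do.call(rbind, table1) else NULL,
    table2 = if (length(table2)) do.call(rbind, table2) else NULL,
    table3 = if (length(table3)) do.call(rbind, table3) else NULL,
    candidates = if (length(candidates)) do.call(rbind, candidates) else NULL,
    conditional = if (length(conditional)) do.call(rbind, conditional)
                  else NULL,
    errors = errors,
    meta = list(seed = config$seed, config = config,
                package_version = as.character(utils::packageVersion("famqtl")),
                thresholds = list(
                  prioritize = config$prioritize_threshold,
                  lod = config$lod_threshold, window_bp = config$window_bp,
                  max_founders = config$max_founders,
                  min_copies = config$min_copies, maf_max = config$maf_max,
                  alpha = config$alpha)),
    study = study), class = "study_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.study_report <- function(x, ...) {
  cat("famqtl study report\n")
  if (!is.null(x$table2)) {
    pri <- unique(x$table2[x$table2$prioritized, c("trait", "family")])
    cat(sprintf("  prioritized: %s\n",
                if (nrow(pri)) paste(sprintf("%s (family %s)", pri$trait,
                                             pri$family), collapse = ", ")
                else "none"))
  }
  if (!is.null(x$table3))
    cat(sprintf("  Bonferroni-significant variants: %s\n",
                paste(unique(x$table3$variant_id), collapse = ", ")))
  if (length(x$errors))
    cat("  errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

fmt_num <- function(x, digits) ifelse(is.na(x), "NA",
                                      formatC(x, format = "f", digits = digits))
fmt_p <- function(p) ifelse(is.na(p), "NA", formatC(p, format = "g", digits = 3))

#' Write a study report to disk
#'
#' Emits `table1.tsv` (variance partitions), `table2.tsv` (per-family QTL
#' counts, with the excess annotated as `"x.x (+y.y)"` for prioritized
#' families only), `table3.tsv` (association results; p-values to 3
#' significant digits, LOD to 2 decimals, percentages to 1 decimal) and a
#' human-readable `summary.txt` recording every threshold applied.  Empty
#' tables are written header-only.
#'
#' @param report a `study_report` from [run_pipeline()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
render_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  t1 <- report$table1 %||% data.frame(trait = character(0))
  wt(t1, "table1.tsv")

  if (!is.null(report$table2)) {
    t2 <- report$table2
    t2$expected_k_fmt <- ifelse(
      t2$prioritized,
      sprintf("%s (+ %s)", fmt_num(t2$expected_k, 1), fmt_num(t2$excess, 1)),
      fmt_num(t2$expected_k, 1))
    wt(t2[, c("trait", "family", "family_size", "expected_k_fmt")],
       "table2.tsv")
  } else {
    wt(data.frame(trait = character(0), family = character(0),
                  family_size = integer(0), expected_k_fmt = character(0)),
       "table2.tsv")
  }

  if (!is.null(report$table3)) {
    t3 <- report$table3
    t3$pvalue <- fmt_p(t3$pvalue)
    t3$lod_unadjusted <- fmt_num(t3$lod_unadjusted, 2)
    t3$lod_adjusted <- fmt_num(t3$lod_adjusted, 2)
    t3$pct_variance_snp <- fmt_num(t3$pct_variance_snp, 1)
    t3$copies_founders <- sprintf("%d (%d)", t3$n_copies,
                                  t3$n_founder_entries)
    wt(t3[, c("trait", "variant_id", "scope", "copies_founders", "pvalue",
              "lod_unadjusted", "lod_adjusted", "pct_variance_snp")],
       "table3.tsv")
  } else {
    wt(data.frame(trait = character(0), variant_id = character(0),
                  scope = character(0), copies_founders = character(0),
                  pvalue = character(0), lod_unadjusted = character(0),
                  lod_adjusted = character(0),
                  pct_variance_snp = character(0)),
       "table3.tsv")
  }

  th <- report$meta$thresholds
  lines <- c("famqtl pipeline summary",
             sprintf("seed: %s", report$meta$seed),
             sprintf("package version: %s", report$meta$package_version),
             "thresholds applied:",
             sprintf("  excess-QTL prioritization threshold: %.2f", th$prioritize),
             sprintf("  linkage LOD threshold: %.2f", th$lod),
             sprintf("  candidate window: %d bp", as.integer(th$window_bp)),
             sprintf("  max entering founders: %d", th$max_founders),
             sprintf("  min rare-allele copies: %d", th$min_copies),
             sprintf("  candidate MAF ceiling: %.3f", th$maf_max),
             sprintf("  Bonferroni family-wise alpha: %.3f", th$alpha))
  if (length(report$errors))
    lines <- c(lines, "errors:",
               sprintf("  %s: %s", names(report$errors),
                       unlist(report$errors)))
  writeLines(lines, file.path(dir, "summary.txt"))
  invisible(dir)
}
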