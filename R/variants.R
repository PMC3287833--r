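#' Linked regions from a family-specific linkage scan
#'
#' Genes whose family-specific LOD reaches `lod_threshold` define candidate
#' regions: a 1-Mbp window centered at the gene position (half-open
#' `[center - 5e5, center + 5e5)`, clipped at position 1), inside which
#' rare variants are extracted for association testing.
#'
#' @param results data frame from [scan_genes()] for one family scope.
#' @param lod_threshold minimum LOD (default 0.60, a pointwise p of 0.05).
#' @param window_bp window width in bp (default 1e6).
#' @return data frame of regions: `gene`, `chrom`, `center`,
#'   `window_start`, `window_end`, `family`, `lod`.
#' @export
linked_regions <- function(results, lod_threshold = 0.60, window_bp = 1e6) {
  hit <- results[results$lod >= lod_threshold, , drop = FALSE]
  if (nrow(hit) == 0L)
    return(data.frame(gene = character(0), chrom = character(0),
                      center = numeric(0), window_start = numeric(0),
                      window_end = numeric(0), family = character(0),
                      lod = numeric(0)))
  half <- window_bp / 2
  data.frame(gene = hit$gene, chrom = hit$chrom, center = hit$pos,
             window_start = pmax(1, hit$pos - half),
             window_end = hit$pos + half,
             family = hit$scope, lod = hit$lod,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Number of founders through which a rare allele enters a family
#'
#' Counts the founders carrying at least one copy of the rare allele (a
#' homozygous founder counts once).  Under Mendelian inheritance without
#' mutation every rare allele must trace to a founder, so carriers among
#' non-founders with no founder carrier indicate inconsistent data and
#' raise a warning.
#'
#' @param ped a [pedigree].
#' @param genotypes named 0/1/2 vector covering the pedigree members.
#' @return integer count of entering founders.
#' @export
founder_entry_count <- function(ped, genotypes) {
  ped <- ensure_pedigree(ped)
  if (!all(ped$id %in% names(genotypes)))
    stop("genotype vector not aligned with pedigree members")
  g <- genotypes[ped$id]
  fnd <- founders(ped)
  nf <- sum(g[fnd] >= 1L)
  if (nf == 0L && any(g[setdiff(ped$id, fnd)] >= 1L))
    warning("rare allele carried by non-founders but no founder: ",
            "inconsistent with Mendelian inheritance without mutation")
  as.integer(nf)
}

#' Filter rare candidate variants in a linked region
#'
#' Keeps variants that (i) fall inside the region's half-open window,
#' (ii) enter the family through at most `max_founders` founders,
#' (iii) have at least `min_copies` copies of the rare allele among the
#' family's members, and (iv) are rare in the combined sample (minor
#' allele frequency below `maf_max`).  Copies are counted as allele
#' copies (a homozygote contributes 2); the carrier count is reported
#' alongside.
#'
#' @param region one row of [linked_regions()] output.
#' @param study a `sim_study` (or compatible list with `variants`,
#'   `genotypes`, `pedigrees`).
#' @param max_founders maximum entering founders (default 2).
#' @param min_copies minimum rare-allele copies in the family (default 5).
#' @param maf_max variants at or above this minor allele frequency in the
#'   combined sample are not candidates (default 0.05).
#' @return data frame of candidates: `variant_id`, `gene_context`,
#'   `family`, `chrom`, `pos`, `copies_in_family`, `carriers_in_family`,
#'   `entering_founders`, plus `carrier_ids` (comma-separated).
#' @export
filter_candidates <- function(region, study, max_founders = 2L,
                              min_copies = 5L, maf_max = 0.05) {
  fam <- region$family
  ped <- study$pedigrees[[fam]]
  if (is.null(ped)) stop("unknown family id: ", fam)
  v <- study$variants
  inwin <- v$chrom == region$chrom &
    v$pos >= region$window_start & v$pos < region$window_end
  out <- list()
  for (i in which(inwin)) {
    g_all <- study$genotypes[, v$id[i]]
    maf <- min(mean(g_all) / 2, 1 - mean(g_all) / 2)
    if (maf >= maf_max) next
    g <- g_all[ped$id]
    copies <- sum(g)
    if (copies < min_copies) next
    nf <- founder_entry_count(ped, g)
    if (nf > max_founders) next
    carriers <- names(g)[g >= 1L]
    out[[length(out) + 1L]] <- data.frame(
      variant_id = v$id[i],
      gene_context = region$gene, family = fam,
      chrom = v$chrom[i], pos = v$pos[i],
      copies_in_family = copies,
      carriers_in_family = length(carriers),
      entering_founders = nf,
      carrier_ids = paste(carriers, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(variant_id = character(0), gene_context = character(0),
                      family = character(0), chrom = character(0),
                      pos = numeric(0), copies_in_family = integer(0),
                      carriers_in_family = integer(0),
                      entering_founders = integer(0),
                      carrier_ids = character(0)))
  do.call(rbind, out)
}

#' Candidate variants over all linked regions of a family
#'
#' Applies [filter_candidates()] to every region and deduplicates variants
#' appearing in overlapping windows by variant id (first region kept).
#'
#' @param regions data frame from [linked_regions()].
#' @param study a `sim_study`.
#' @inheritParams filter_candidates
#' @return combined candidate data frame, unique by `variant_id`.
#' @export
collect_candidates <- function(regions, study, max_founders = 2L,
                               min_copies = 5L, maf_max = 0.05) {
  cands <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i)
    filter_candidates(regions[i, ], study, max_founders, min_copies,
                      maf_max)))
  if (is.null(cands) || nrow(cands) == 0L)
    return(filter_candidates(data.frame(gene = "none", chrom = "none",
                                        center = 0, window_start = 1,
                                        window_end = 1,
                                        family = names(study$pedigrees)[1],
                                        lod = 0), study))
  cands[!duplicated(cands$variant_id), , drop = FALSE]
}
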