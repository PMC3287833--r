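#' Construct and validate a pedigree
#'
#' A pedigree is a data frame with one row per individual and columns
#' `family`, `id`, `father`, `mother` (both `NA` for founders) and `sex`
#' (1 = male, 2 = female).  Validation enforces the structural invariants:
#' unique ids, both parents present or both absent, referenced parents
#' existing in the pedigree with consistent sexes, and an acyclic parent
#' graph.
#'
#' @param family_id family identifier (recycled).
#' @param id character vector of individual identifiers, unique within the
#'   family.
#' @param father,mother identifiers of the parents, `NA` (or `"0"`) for
#'   founders.
#' @param sex integer sex code: 1 male, 2 female.
#' @return an object of class `pedigree` (a validated data frame).
#' @examples
#' trio <- pedigree("fam1", c("p1", "p2", "c1"),
#'                  father = c(NA, NA, "p1"),
#'                  mother = c(NA, NA, "p2"),
#'                  sex = c(1, 2, 1))
#' founders(trio)
#' @export
pedigree <- function(family_id, id, father = NA, mother = NA, sex) {
  ped <- data.frame(
    family = rep_len(as.character(family_id), length(id)),
    id = as.character(id),
    father = rep_len(as.character(father), length(id)),
    mother = rep_len(as.character(mother), length(id)),
    sex = as.integer(sex),
    stringsAsFactors = FALSE
  )
  ped$father[ped$father %in% c("0", "")] <- NA_character_
  ped$mother[ped$mother %in% c("0", "")] <- NA_character_
  validate_pedigree(ped)
}

#' Validate pedigree invariants
#'
#' @param ped a data frame with columns `family`, `id`, `father`, `mother`,
#'   `sex`.
#' @return the validated pedigree with class `pedigree`.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped),
            all(c("family", "id", "father", "mother", "sex") %in% names(ped)))
  if (nrow(ped) == 0L) stop("pedigree has no members")
  if (anyDuplicated(ped$id))
    stop("duplicated individual id(s): ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  if (length(unique(ped$family)) != 1L)
    stop("a pedigree holds exactly one family; use read_ped() for multi-family files")
  if (!all(ped$sex %in% c(1L, 2L)))
    stop("sex must be coded 1 (male) or 2 (female)")
  one_parent <- xor(is.na(ped$father), is.na(ped$mother))
  if (any(one_parent))
    stop("individual(s) with exactly one recorded parent: ",
         paste(ped$id[one_parent], collapse = ", "))
  nonf <- !is.na(ped$father)
  missing_f <- nonf & !(ped$father %in% ped$id)
  missing_m <- nonf & !(ped$mother %in% ped$id)
  if (any(missing_f | missing_m))
    stop("referenced parent(s) not in pedigree for: ",
         paste(ped$id[missing_f | missing_m], collapse = ", "))
  fa_sex <- ped$sex[match(ped$father[nonf], ped$id)]
  mo_sex <- ped$sex[match(ped$mother[nonf], ped$id)]
  if (any(fa_sex != 1L))
    stop("father with non-male sex for: ",
         paste(ped$id[nonf][fa_sex != 1L], collapse = ", "))
  if (any(mo_sex != 2L))
    stop("mother with non-female sex for: ",
         paste(ped$id[nonf][mo_sex != 2L], collapse = ", "))
  ord <- tryCatch(ped_order(ped), error = function(e) stop(e))
  attr(ped, "topo") <- ord
  class(ped) <- unique(c("pedigree", class(ped)))
  ped
}

# Topological order of a pedigree: parents before children, ties broken by
# input order.  Errors (naming an individual) if the parent graph has a cycle.
ped_order <- function(ped) {
  n <- nrow(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  depth <- rep(NA_integer_, n)
  depth[is.na(fa)] <- 0L
  # iterative relaxation; a cycle leaves some depth unresolved
  for (pass in seq_len(n + 1L)) {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    progress <- FALSE
    for (i in todo) {
      df <- depth[fa[i]]; dm <- depth[mo[i]]
      if (!is.na(df) && !is.na(dm)) {
        depth[i] <- max(df, dm) + 1L
        progress <- TRUE
      }
    }
    if (!progress) {
      stop("pedigree cycle detected involving individual(s): ",
           paste(ped$id[is.na(depth)], collapse = ", "))
    }
  }
  order(depth, seq_len(n))
}

#' Founders of a pedigree
#'
#' Founders are exactly the members with no recorded parents; absent
#' mutation they are the only route by which a new allele enters the family.
#'
#' @param ped a `pedigree`.
#' @return character vector of founder ids.
#' @export
founders <- function(ped) {
  ped$id[is.na(ped$father) & is.na(ped$mother)]
}

#' Kinship matrix of a pedigree
#'
#' Computes the kinship coefficients phi(i, j) -- the probability that one
#' allele drawn at random from i and one from j are identical by descent --
#' by the standard recursive rule, processing individuals in ancestral
#' order: for founder i, phi(i, i) = 1/2 and phi(i, j) = 0 for any j that is
#' not a descendant; for non-founder i with parents f and m,
#' phi(i, i) = (1 + phi(f, m)) / 2 and phi(i, j) = (phi(f, j) + phi(m, j)) / 2
#' for any j processed before i.  Inbred (looped) pedigrees are handled by
#' the same recursion.
#'
#' @param ped a `pedigree`.
#' @return symmetric numeric matrix with dimnames equal to the member ids,
#'   in the pedigree's input order.  Twice this matrix (2 Phi) is the
#'   additive genetic covariance kernel used by the variance-components
#'   machinery.
#' @export
kinship_matrix <- function(ped) {
  ped <- ensure_pedigree(ped)
  n <- nrow(ped)
  ord <- attr(ped, "topo")
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  K <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  pos <- integer(n)  # processing rank of each row index
  pos[ord] <- seq_len(n)
  for (r in seq_len(n)) {
    i <- ord[r]
    if (is.na(fa[i])) {
      K[i, i] <- 0.5
    } else {
      K[i, i] <- 0.5 * (1 + K[fa[i], mo[i]])
      earlier <- ord[seq_len(r - 1L)]
      K[i, earlier] <- 0.5 * (K[fa[i], earlier] + K[mo[i], earlier])
      K[earlier, i] <- K[i, earlier]
    }
  }
  K
}

ensure_pedigree <- function(ped) {
  if (!inherits(ped, "pedigree") || is.null(attr(ped, "topo")))
    ped <- validate_pedigree(as.data.frame(ped))
  ped
}

#' Read pedigrees from a PLINK PED/FAM file
#'
#' Expects whitespace-delimited columns family, id, father, mother, sex
#' (optionally followed by a phenotype column, which is ignored), with "0"
#' as the missing-parent code.  Each family id yields one validated
#' [pedigree].
#'
#' @param path path to the PED/FAM file.
#' @return named list of `pedigree` objects, one per family.
#' @export
read_ped <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 5L)
    stop("PED file must have at least 5 columns (family id father mother sex)")
  names(tab)[1:5] <- c("family", "id", "father", "mother", "sex")
  peds <- lapply(split(tab, factor(tab$family, levels = unique(tab$family))),
                 function(fam) {
                   pedigree(fam$family, fam$id, fam$father, fam$mother,
                            as.integer(fam$sex))
                 })
  peds
}

#' Write pedigrees to a PLINK PED/FAM file
#'
#' @param peds a `pedigree` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(peds, path) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  rows <- do.call(rbind, lapply(peds, function(p) {
    data.frame(family = p$family, id = p$id,
               father = ifelse(is.na(p$father), "0", p$father),
               mother = ifelse(is.na(p$mother), "0", p$mother),
               sex = p$sex, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree '%s': %d members, %d founders\n",
              x$family[1], nrow(x), length(founders(x))))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
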