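#' Genomic relatedness matrix (VanRaden)
#'
#' Computes the realized additive relationship matrix
#' `G = (M - P)(M - P)' / (2 * sum(p_i (1 - p_i)))` from an allele-dosage
#' matrix, where `M` holds genotypes recoded to -1/0/1 (dosage - 1) and `P`
#' holds `2 (p_i - 0.5)` per locus. Monomorphic loci are dropped, missing
#' genotypes are mean-imputed per locus before recoding, and individuals
#' with excessive missingness are flagged (never silently dropped).
#'
#' @param geno n x m matrix of 0/1/2 allele dosages (NA = missing),
#'   individuals in rows with ids in rownames.
#' @param allele_freqs Optional per-locus frequencies of the counted
#'   (alternate) allele; defaults to observed sample frequencies.
#' @param max_missing_locus,max_missing_ind Missingness ceilings; loci above
#'   the ceiling are dropped, individuals above it are flagged.
#' @return The n x n relatedness matrix with attributes `provenance`
#'   (`"genomic"`), `relatedness_variance` (variance of the off-diagonal
#'   entries), `n_loci_used` and `flagged_individuals`.
#' @export
vanraden_grm <- function(geno, allele_freqs = NULL,
                         max_missing_locus = 0.2, max_missing_ind = 0.2) {
  geno <- as.matrix(geno)
  if (nrow(geno) < 2) stop("need at least 2 individuals")
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("ind%03d", seq_len(nrow(geno)))
  miss_ind <- rowMeans(is.na(geno))
  flagged <- rownames(geno)[miss_ind > max_missing_ind]
  miss_loc <- colMeans(is.na(geno))
  keep <- miss_loc <= max_missing_locus
  geno <- geno[, keep, drop = FALSE]
  p <- if (is.null(allele_freqs)) colMeans(geno, na.rm = TRUE) / 2
       else allele_freqs[keep]
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all retained loci are monomorphic")
  if (any(!poly))
    message("dropping ", sum(!poly), " monomorphic loci")
  geno <- geno[, poly, drop = FALSE]
  p <- p[poly]
  ## mean imputation on the dosage scale, then the affine recode cancels:
  ## Z = (dosage - 1) - 2(p - 0.5) = dosage - 2p
  Z <- sweep(geno, 2, 2 * p)
  Z[is.na(Z)] <- 0                        # imputed dosage 2p gives Z = 0
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(geno), rownames(geno))
  off <- G[lower.tri(G)]
  structure(G, provenance = "genomic",
            relatedness_variance = var(off),
            n_loci_used = ncol(geno),
            flagged_individuals = flagged)
}

## Topological ordering of a pedigree; errors on cycles / unknown parents.
order_pedigree <- function(pedigree, founders = character(0)) {
  ids <- pedigree$id
  if (anyDuplicated(ids)) stop("duplicated pedigree ids")
  known <- c(founders, ids)
  for (col in c("mother", "father")) {
    bad <- !is.na(pedigree[[col]]) & !(pedigree[[col]] %in% known)
    if (any(bad))
      stop("unknown ", col, " id in pedigree record for '",
           pedigree$id[which(bad)[1]], "'")
  }
  placed <- founders
  order_out <- character(0)
  remaining <- pedigree
  while (nrow(remaining) > 0) {
    ready <- (is.na(remaining$mother) | remaining$mother %in% placed) &
             (is.na(remaining$father) | remaining$father %in% placed)
    if (!any(ready))
      stop("pedigree cycle involving '", remaining$id[1], "'")
    order_out <- c(order_out, remaining$id[ready])
    placed <- c(placed, remaining$id[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }
  order_out
}

## Core recursion: extend a founder relationship block down a pedigree.
## a(o, z) = (a(mother, z) + a(father, z)) / 2 with unknown parents
## contributing 0; a(o, o) = 1 + a(mother, father) / 2.
nrm_extend <- function(founder_A, pedigree) {
  fid <- rownames(founder_A) %||% character(0)
  ord <- order_pedigree(pedigree, founders = fid)
  ped <- pedigree[match(ord, pedigree$id), , drop = FALSE]
  all_id <- c(fid, ord)
  n <- length(all_id)
  A <- matrix(0, n, n, dimnames = list(all_id, all_id))
  nf <- length(fid)
  if (nf) A[seq_len(nf), seq_len(nf)] <- founder_A
  idx <- setNames(seq_len(n), all_id)
  for (r in seq_len(nrow(ped))) {
    o <- idx[ped$id[r]]
    m <- if (is.na(ped$mother[r])) NA_integer_ else idx[ped$mother[r]]
    f <- if (is.na(ped$father[r])) NA_integer_ else idx[ped$father[r]]
    prev <- seq_len(o - 1L)
    am <- if (is.na(m)) 0 else A[m, prev]
    af <- if (is.na(f)) 0 else A[f, prev]
    A[o, prev] <- A[prev, o] <- (am + af) / 2
    A[o, o] <- 1 + (if (is.na(m) || is.na(f)) 0 else A[m, f] / 2)
  }
  A
}

#' Pedigree-based additive (numerator) relationship matrix
#'
#' Tabular recursive computation of Wright's numerator relationship matrix.
#' Founders (individuals whose parents are both unknown or absent from the
#' table) are taken as unrelated and non-inbred. Self-relatedness is
#' `1 + f` with `f` the inbreeding coefficient.
#'
#' @param pedigree `data.frame` with columns `id`, `mother`, `father`
#'   (NA = unknown). Any parent id not itself listed is treated as a founder.
#' @return Relatedness matrix over all ids, attribute `provenance =
#'   "pedigree"`.
#' @export
pedigree_nrm <- function(pedigree) {
  pedigree <- as.data.frame(pedigree)
  stopifnot(all(c("id", "mother", "father") %in% names(pedigree)))
  implicit <- setdiff(c(pedigree$mother, pedigree$father), c(pedigree$id, NA))
  if (length(implicit))
    pedigree <- rbind(
      data.frame(id = implicit, mother = NA_character_,
                 father = NA_character_),
      pedigree[c("id", "mother", "father")])
  founder <- is.na(pedigree$mother) & is.na(pedigree$father)
  fA <- diag(sum(founder))
  dimnames(fA) <- list(pedigree$id[founder], pedigree$id[founder])
  A <- nrm_extend(fA, pedigree[!founder, , drop = FALSE])
  structure(A, provenance = "pedigree")
}

#' Hybrid two-generation relatedness matrix
#'
#' Combines a realized genomic relationship matrix among adults (G1) with
#' pedigree links to the sapling generation (G2): the G1 block is the GRM
#' unchanged, and G1-G2 / G2-G2 entries follow the numerator-relationship
#' recursion using the genomic block as founder relatedness. Unknown parents
#' contribute zero relatedness.
#'
#' @param grm_g1 Genomic relatedness among G1 ids (dimnames required).
#' @param pedigree `data.frame` with `id`, `mother`, `father` for G2; parent
#'   ids must appear in `grm_g1` or be NA.
#' @return Relatedness matrix over G1 then G2 ids, `provenance = "hybrid"`.
#' @export
hybrid_relatedness <- function(grm_g1, pedigree) {
  grm_g1 <- as.matrix(grm_g1)
  if (is.null(rownames(grm_g1))) stop("'grm_g1' needs ids in dimnames")
  pedigree <- as.data.frame(pedigree)
  par_ids <- setdiff(c(pedigree$mother, pedigree$father), NA)
  missing <- setdiff(par_ids, rownames(grm_g1))
  if (length(missing))
    stop("pedigree parents absent from the G1 matrix: ",
         paste(head(missing, 3), collapse = ", "))
  A <- nrm_extend(grm_g1, pedigree[c("id", "mother", "father")])
  structure(A, provenance = "hybrid")
}

#' Condition a relatedness matrix to be positive definite
#'
#' If the smallest eigenvalue falls below `eps`, bends the matrix by adding
#' `eps - lambda_min` to the diagonal (off-diagonals untouched); otherwise
#' returns the input unchanged.
#'
#' @param G Symmetric relatedness matrix.
#' @param eps Eigenvalue floor (default `1e-8`).
#' @return Conditioned matrix with attribute `bending_applied`.
#' @export
condition_matrix <- function(G, eps = 1e-8) {
  G <- as.matrix(G)
  lam <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  at <- attributes(G)
  if (lam < eps) {
    diag(G) <- diag(G) + (eps - lam)
    attributes(G) <- utils::modifyList(at, attributes(G))
    attr(G, "bending_applied") <- TRUE
  } else {
    attr(G, "bending_applied") <- FALSE
  }
  G
}
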