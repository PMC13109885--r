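# Relationship matrices: pedigree A (tabular method), genomic G (VanRaden,
# optionally SNP-weighted), the 0.95/0.05 blend Gw, and the single-step
# H-inverse that joins pedigree and genomic information.

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Builds the additive (numerator) relationship matrix A from a pedigree by
#' the tabular recursion: `A[i,i] = 1 + 0.5 * A[sire, dam]` and, for an
#' earlier individual j, `A[i,j] = 0.5 * (A[j, sire] + A[j, dam])`, with an
#' unknown parent contributing zero. Diagonal elements therefore equal one
#' plus the individual's inbreeding coefficient.
#'
#' @param ped data.frame with columns `id`, `sire`, `dam` (0 or NA = unknown
#'   parent), topologically ordered so parents precede offspring.
#' @return symmetric matrix with `id` dimnames, attribute `kind = "A"`.
#' @export
#' @examples
#' ped <- data.frame(id = c("f1", "f2", "o1"), sire = c(0, 0, "f1"),
#'                   dam = c(0, 0, "f2"))
#' a_matrix(ped)["f1", "o1"]  # 0.5
a_matrix <- function(ped) {
  ped <- normalize_pedigree(ped)
  n <- nrow(ped)
  s <- ped$sire_idx
  d <- ped$dam_idx
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- 0.5 * ((if (si > 0L) A[j, si] else 0) +
                    (if (di > 0L) A[j, di] else 0))
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + 0.5 * (if (si > 0L && di > 0L) A[si, di] else 0)
  }
  structure(A, kind = "A")
}

# Validate/normalize a pedigree data.frame: ids unique, parents precede
# offspring (detects cycles/forward references), parent ids resolved to row
# indices with 0 = unknown.
normalize_pedigree <- function(ped) {
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  id <- as.character(ped$id)
  if (anyDuplicated(id)) stop("duplicated ids in pedigree: ",
                              paste(unique(id[duplicated(id)]), collapse = ", "))
  resolve <- function(p) {
    p <- as.character(p)
    p[is.na(p) | p == "0" | p == ""] <- NA
    idx <- match(p, id)
    if (any(!is.na(p) & is.na(idx)))
      stop("pedigree parent not found among ids: ",
           paste(unique(p[!is.na(p) & is.na(idx)]), collapse = ", "))
    idx[is.na(idx)] <- 0L
    idx
  }
  s <- resolve(ped$sire)
  d <- resolve(ped$dam)
  rows <- seq_along(id)
  if (any(s >= rows) || any(d >= rows))
    stop("pedigree is not topologically ordered (or contains a cycle): ",
         "parents must precede offspring")
  out <- data.frame(id = id, sire_idx = s, dam_idx = d,
                    stringsAsFactors = FALSE)
  if ("generation" %in% names(ped)) out$generation <- ped$generation
  out
}

#' VanRaden genomic relationship matrix, optionally SNP-weighted
#'
#' Computes `G = Z D Z' / sum(2 p_i (1 - p_i))` where `Z` is the dosage matrix
#' column-centered by twice the counted-allele frequency `p_i` and `D` is a
#' diagonal matrix of per-SNP weights (identity by default). `p_i` is the
#' observed frequency of the counted (dosage) allele; it is not folded to the
#' minor allele because column centering requires the counted-allele frequency.
#'
#' @param dosages individuals x markers numeric matrix with values in
#'   \{0, 1, 2\} and no missing entries (mean-impute first; see
#'   [impute_dosages()]).
#' @param weights nonnegative per-marker weights (length = number of markers).
#'   They are used as supplied; see [normalize_weights()] for the
#'   trace-to-M normalization used by the weighting iteration.
#' @param freqs optional allele frequencies to center with; computed from
#'   `dosages` when omitted.
#' @return symmetric matrix with individual-id dimnames, attribute
#'   `kind = "G"`.
#' @export
g_matrix <- function(dosages, weights = NULL, freqs = NULL) {
  stopifnot(is.matrix(dosages), ncol(dosages) >= 1L)
  if (anyNA(dosages)) stop("dosages contain missing values; impute first")
  M <- ncol(dosages)
  p <- if (is.null(freqs)) colMeans(dosages) / 2 else freqs
  if (any(p <= 0 | p >= 1))
    stop("monomorphic marker(s) present (allele frequency 0 or 1); ",
         "run qc_filter() before building G")
  if (is.null(weights)) weights <- rep(1, M)
  if (length(weights) != M) stop("weights length must equal marker count")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and nonnegative")
  Z <- sweep(dosages, 2L, 2 * p, "-")
  denom <- sum(2 * p * (1 - p))
  Zw <- sweep(Z, 2L, sqrt(weights), "*")
  G <- tcrossprod(Zw) / denom
  dimnames(G) <- list(rownames(dosages), rownames(dosages))
  structure(symmetrize(G), kind = "G")
}

#' Blend a genomic matrix with its pedigree counterpart
#'
#' `Gw = 0.95 * G + 0.05 * A22`, the standard weighting that guarantees an
#' invertible genomic relationship matrix for the single-step model.
#'
#' @param G genomic relationship matrix over the genotyped individuals.
#' @param A22 pedigree relationship submatrix for the same individuals, in the
#'   same order (checked by dimnames when present). Passing the identity
#'   yields the `0.95 G + 0.05 I` blend used for plain GBLUP.
#' @param tau weight on `G` (default 0.95).
#' @return blended matrix, attribute `kind = "Gw"`.
#' @export
blend_gw <- function(G, A22, tau = 0.95) {
  stopifnot(all(dim(G) == dim(A22)))
  if (!is.null(rownames(G)) && !is.null(rownames(A22)) &&
      !identical(rownames(G), rownames(A22)))
    stop("id order of G and A22 differs")
  structure(symmetrize(tau * G + (1 - tau) * A22), kind = "Gw")
}

#' Single-step H-inverse
#'
#' Assembles the inverse of the joint pedigree-genomic relationship matrix:
#' `H^-1 = A^-1 + [0 0; 0 Gw^-1 - A22^-1]`, with the correction applied on
#' the genotyped block.
#'
#' @param Ainv inverse of the full pedigree relationship matrix (all
#'   individuals).
#' @param A22inv inverse of the pedigree submatrix of the genotyped
#'   individuals.
#' @param Gwinv inverse of the blended genomic matrix for the same genotyped
#'   individuals, same order.
#' @param genotyped indices (or ids, when `Ainv` has dimnames) of the
#'   genotyped individuals within `Ainv`'s order.
#' @return matrix with attribute `kind = "Hinv"`.
#' @export
h_inverse <- function(Ainv, A22inv, Gwinv, genotyped) {
  stopifnot(all(dim(A22inv) == dim(Gwinv)))
  if (is.character(genotyped)) {
    genotyped <- match(genotyped, rownames(Ainv))
    if (anyNA(genotyped)) stop("genotyped ids not found in Ainv dimnames")
  }
  stopifnot(length(genotyped) == nrow(Gwinv))
  H <- Ainv
  H[genotyped, genotyped] <- H[genotyped, genotyped] + (Gwinv - A22inv)
  structure(symmetrize(H), kind = "Hinv")
}

#' Trace-normalize a SNP weight vector
#'
#' Rescales nonnegative weights so their sum (the trace of the diagonal
#' weight matrix D) equals the marker count M, the normalization applied at
#' every weighting iteration.
#'
#' @param w nonnegative weights.
#' @return rescaled weights summing to `length(w)`.
#' @export
normalize_weights <- function(w) {
  if (any(!is.finite(w))) stop("non-finite weight at marker ",
                               which(!is.finite(w))[1])
  if (any(w < 0)) stop("negative weight at marker ", which(w < 0)[1])
  s <- sum(w)
  if (s == 0) stop("all weights zero; cannot normalize")
  w * length(w) / s
}
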