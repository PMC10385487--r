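## Genomic relationship matrices: VanRaden additive and Vitezica dominance.

## Internal: validate a relationship matrix (symmetry, near-PSD) and clip
## negligible negative eigenvalues.  Eigenvalues below -1e-8 are an error;
## values in (-1e-8, 0) are numerical noise and clipped to zero.
.check_relmatrix <- function(G, kind) {
  if (max(abs(G - t(G))) > 1e-10) stop(kind, " matrix is not symmetric")
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(1, max(abs(ev)))
  if (min(ev) < -1e-8 * scale)
    stop(kind, " matrix has a substantially negative eigenvalue (",
         format(min(ev)), ")")
  G
}

#' VanRaden additive genomic relationship matrix
#'
#' Computes `G = Z Z' / (2 * sum(p_j * (1 - p_j)))` where `Z` is the dosage
#' matrix centred by twice the allele frequencies computed from the matrix
#' itself. Applied to the inbred parents it gives the parental kinship `Gp`
#' (diagonal near 2 for fully homozygous lines); applied to hybrid dosages
#' it gives the hybrid additive kinship `Gh`.
#'
#' @param g Dosage matrix (individuals x SNPs); missing calls are
#'   mean-imputed.
#' @return Symmetric positive semi-definite relationship matrix with the
#'   individuals' labels.
#' @export
grm_vanraden <- function(g) {
  g <- impute_mean(g)
  p <- colMeans(g) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all SNPs monomorphic: VanRaden denominator is zero")
  Z <- sweep(g, 2, 2 * p)
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(g), rownames(g))
  .check_relmatrix(G, "additive relationship")
}

#' Vitezica dominance relationship matrix
#'
#' Recodes each SNP's dosages to the classical dominance contrasts
#' (`0 -> -2p^2`, `1 -> 2pq`, `2 -> -2q^2` with `p` the alternate allele
#' frequency of that SNP) and forms `D = W W' / sum((2 p_j q_j)^2)`. Used as
#' the covariance kernel of specific combining ability among hybrids.
#'
#' @param g Dosage matrix of the hybrids; missing calls are mean-imputed and
#'   dosages are rounded to the nearest genotype class for the recoding.
#' @return Symmetric positive semi-definite dominance relationship matrix.
#' @export
dominance_matrix <- function(g) {
  g <- impute_mean(g)
  p <- colMeans(g) / 2
  q <- 1 - p
  denom <- sum((2 * p * q)^2)
  if (denom <= 0)
    stop("all SNPs monomorphic: dominance denominator is zero")
  gi <- round(g)
  W <- matrix(0, nrow(g), ncol(g))
  for (dose in 0:2) {
    code <- switch(as.character(dose),
                   "0" = -2 * p^2, "1" = 2 * p * q, "2" = -2 * q^2)
    idx <- gi == dose
    W[idx] <- matrix(code, nrow(g), ncol(g), byrow = TRUE)[idx]
  }
  D <- tcrossprod(W) / denom
  dimnames(D) <- list(rownames(g), rownames(g))
  .check_relmatrix(D, "dominance relationship")
}
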