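## Marker QC: allele frequencies, MAF/missingness filtering, PIC,
## kinship-corrected LD (rv2) pruning, and marker PCA.

#' Alternate-allele frequencies of a dosage matrix
#'
#' @param g Dosage matrix (individuals x SNPs, values 0/1/2, NA allowed).
#' @return Per-SNP alternate allele frequency computed on non-missing calls.
#' @export
allele_freq <- function(g) {
  g <- as.matrix(g)
  colMeans(g, na.rm = TRUE) / 2
}

#' Filter SNPs on minor allele frequency and missingness
#'
#' Keeps SNPs with minor allele frequency at least `maf_min` (computed on
#' non-missing calls, boundary inclusive) and missing-call fraction at most
#' `miss_max`. Column order is preserved.
#'
#' @param g Dosage matrix with SNP column names.
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param miss_max Maximum fraction of missing calls per SNP (default 0.10).
#' @return Character vector of retained SNP IDs.
#' @export
filter_snps <- function(g, maf_min = 0.05, miss_max = 0.10) {
  g <- as.matrix(g)
  if (nrow(g) == 0L || ncol(g) == 0L) stop("empty genotype matrix")
  if (is.null(colnames(g))) colnames(g) <- paste0("snp", seq_len(ncol(g)))
  p <- allele_freq(g)
  maf <- pmin(p, 1 - p)
  miss <- colMeans(is.na(g))
  keep <- !is.na(maf) & maf >= maf_min & miss <= miss_max
  if (!any(keep)) stop("all SNPs removed by MAF/missingness filtering")
  colnames(g)[keep]
}

#' Polymorphism information content of a biallelic SNP
#'
#' Botstein's PIC for a biallelic marker,
#' `1 - (p^2 + q^2) - 2 p^2 q^2` with `q = 1 - p`. Maximal (0.375) at
#' `p = 0.5` and symmetric in `p` and `q`.
#'
#' @param p Allele frequency (vectorized), in `[0, 1]`.
#' @return PIC value(s) in `[0, 0.375]`.
#' @export
pic <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("allele frequency must lie in [0, 1]")
  q <- 1 - p
  1 - (p^2 + q^2) - 2 * p^2 * q^2
}

## Internal: whitening factor for a kinship matrix; inverse of the upper
## Cholesky transpose so that cov(L^-1 x) is proportional to I under k.
.whiten_chol <- function(k) {
  ch <- tryCatch(chol(k), error = function(e) NULL)
  if (is.null(ch))
    stop("kinship matrix is singular or not positive definite; ",
         "add a small ridge (e.g. k + 1e-6 * diag(nrow(k))) before LD pruning")
  ch
}

#' Kinship-corrected linkage disequilibrium between two SNPs
#'
#' Squared correlation between two dosage vectors after both are whitened by
#' the inverse Cholesky factor of a kinship matrix, following the
#' relatedness-corrected LD construction of Mangin and colleagues. Shared
#' population history inflates the plain r2 statistic; whitening by the
#' kinship removes that bias. With an identity kinship this reduces exactly
#' to the squared Pearson correlation.
#'
#' @param x_a,x_b Dosage vectors of equal length.
#' @param k Kinship (relationship) matrix of the same individuals, positive
#'   definite.
#' @return Squared correlation in `[0, 1]`.
#' @export
ld_rv2 <- function(x_a, x_b, k) {
  if (length(x_a) != length(x_b)) stop("dosage vectors differ in length")
  if (nrow(k) != length(x_a)) stop("kinship not conformable with dosages")
  ch <- .whiten_chol(k)
  za <- backsolve(ch, x_a, transpose = TRUE)
  zb <- backsolve(ch, x_b, transpose = TRUE)
  one <- backsolve(ch, rep(1, length(x_a)), transpose = TRUE)
  ## GLS centering: project out the whitened intercept
  za <- za - one * sum(one * za) / sum(one * one)
  zb <- zb - one * sum(one * zb) / sum(one * one)
  denom <- sum(za^2) * sum(zb^2)
  if (denom <= 0) return(0)
  min(1, sum(za * zb)^2 / denom)
}

#' Prune SNPs in high kinship-corrected LD
#'
#' Computes all pairwise rv2 values among the SNPs of `g` (whitened once by
#' the supplied kinship) and greedily retains markers so that no retained
#' pair reaches `rv2_max`. Candidates are scanned in order of decreasing
#' informativeness (PIC, ties broken by genome order), so within any
#' conflicting pair or clique the highest-PIC site survives. The result is
#' deterministic and reported in genome order.
#'
#' @param g Dosage matrix (no missing values; filter and impute first).
#' @param k Kinship matrix for whitening (e.g. the VanRaden GRM of `g`).
#' @param rv2_max LD threshold at or above which two SNPs conflict
#'   (default 0.5).
#' @return Character vector of retained SNP IDs in genome order.
#' @export
prune_ld <- function(g, k, rv2_max = 0.5) {
  g <- as.matrix(g)
  if (anyNA(g)) stop("missing dosages: impute before LD pruning")
  if (is.null(colnames(g))) colnames(g) <- paste0("snp", seq_len(ncol(g)))
  m <- ncol(g)
  if (m <= 1L) return(colnames(g))
  ch <- .whiten_chol(k)
  Zt <- backsolve(ch, g, transpose = TRUE)
  one <- backsolve(ch, rep(1, nrow(g)), transpose = TRUE)
  proj <- drop(crossprod(one, Zt)) / sum(one * one)
  Zt <- Zt - outer(one, proj)
  norms <- sqrt(colSums(Zt^2))
  norms[norms == 0] <- 1
  Zt <- sweep(Zt, 2, norms, "/")
  R2 <- crossprod(Zt)^2
  snp_pic <- pic(allele_freq(g))
  ord <- order(-snp_pic, seq_len(m))
  kept <- integer(0)
  for (j in ord) {
    if (!length(kept) || all(R2[j, kept] < rv2_max)) kept <- c(kept, j)
  }
  colnames(g)[sort(kept)]
}

#' Mean-impute missing dosages
#'
#' Replaces missing calls by the SNP's mean dosage over non-missing calls.
#'
#' @param g Dosage matrix.
#' @return Matrix without missing values.
#' @export
impute_mean <- function(g) {
  g <- as.matrix(g)
  if (!anyNA(g)) return(g)
  mu <- colMeans(g, na.rm = TRUE)
  idx <- which(is.na(g), arr.ind = TRUE)
  g[idx] <- mu[idx[, 2]]
  g
}

#' Principal component analysis of a marker matrix
#'
#' Column-centres the dosage matrix (missing calls mean-imputed first) and
#' applies a singular value decomposition; scores are the left singular
#' vectors scaled by the singular values, and explained-variance fractions
#' come from the squared singular values.
#'
#' @param g Dosage matrix (individuals x SNPs).
#' @return A list of class `hgp_pca` with `scores` (individuals x
#'   components), `eigenvalues` (of the marker covariance matrix),
#'   `varfrac`, and `cumvar`.
#' @export
snp_pca <- function(g) {
  g <- impute_mean(g)
  n <- nrow(g)
  if (n < 2L) stop("PCA needs at least two lines")
  Z <- scale(g, center = TRUE, scale = FALSE)
  sv <- svd(Z)
  d2 <- sv$d^2
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  rownames(scores) <- rownames(g)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  vf <- if (sum(d2) > 0) d2 / sum(d2) else rep(0, length(d2))
  structure(list(scores = scores, eigenvalues = d2 / (n - 1),
                 varfrac = vf, cumvar = cumsum(vf)),
            class = "hgp_pca")
}
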