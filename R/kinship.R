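#' Standardize a genotype panel
#'
#' Applies the per-SNP affine transform
#' `(g_ij - 2 p_j) / sqrt(2 p_j (1 - p_j))`, centering each column at its
#' Hardy-Weinberg mean and scaling by the binomial standard deviation.
#' Missing genotypes are imputed to 0 after standardization, i.e. to the
#' column mean, the standard convention when building genetic relationship
#' matrices.
#'
#' @param panel a [GenotypePanel-class] with MAFs strictly in (0, 1).
#' @return n x p numeric matrix of standardized genotypes, dimnames from
#'   the panel identifiers.
#' @examples
#' p <- GenotypePanel(matrix(c(0, 1, 2), 3, 1), maf = 0.25)
#' standardizeGenotypes(p)
#' @export
standardizeGenotypes <- function(panel) {
  stopifnot(is(panel, "GenotypePanel"))
  pj <- maf(panel)
  mono <- pj <= 0 | pj >= 1
  if (any(mono))
    stop("monomorphic SNP(s): ", paste(snpIds(panel)[mono], collapse = ", "))
  G <- genotypes(panel)
  Gt <- sweep(G, 2, 2 * pj, "-")
  Gt <- sweep(Gt, 2, sqrt(2 * pj * (1 - pj)), "/")
  Gt[is.na(Gt)] <- 0
  dimnames(Gt) <- list(sampleIds(panel), snpIds(panel))
  Gt
}

#' Genetic relationship matrix from standardized genotypes
#'
#' Computes `K = G_std G_std' / p`, the standardized cross-product GRM
#' (the PLINK `--make-rel` convention). For genotypes in Hardy-Weinberg
#' proportions the average diagonal is close to 1.
#'
#' @param Gstd n x p matrix of standardized genotypes
#'   (see [standardizeGenotypes()]).
#' @return n x n symmetric matrix.
#' @export
computeGRM <- function(Gstd) {
  Gstd <- as.matrix(Gstd)
  p <- ncol(Gstd)
  if (p == 0) stop("no SNPs: cannot compute a GRM from zero columns")
  K <- tcrossprod(Gstd) / p
  (K + t(K)) / 2
}

#' Gene-by-environment kinship
#'
#' Masks or down-weights kinship by exposure similarity. For a binary
#' exposure, `K_D[i, j] = K[i, j]` when `D_i == D_j` and 0 otherwise. For a
#' continuous exposure, `K_D[i, j] = K[i, j] (1 - d(D_i, D_j))` where `d`
#' is a distance with range [0, 1] (default: absolute difference divided by
#' the exposure range). The diagonal of `K_D` always equals the diagonal of
#' `K`.
#'
#' @param K n x n symmetric kinship matrix.
#' @param D length-n exposure vector.
#' @param kind `"binary"` or `"continuous"`.
#' @param distance for the continuous kind, a vectorized function
#'   `d(x, y)` mapping into [0, 1].
#' @return A [KinshipPair-class] holding `K`, `K_D` and the exposure.
#' @examples
#' K <- matrix(c(1, 0.5, 0.5, 1), 2)
#' gxeKinshipMatrix(buildGxEKinship(K, c(1, 0), kind = "binary"))
#' @export
buildGxEKinship <- function(K, D, kind = c("binary", "continuous"),
                            distance = NULL) {
  kind <- match.arg(kind)
  K <- as.matrix(K)
  stopifnot(length(D) == nrow(K))
  if (kind == "binary") {
    if (length(unique(D)) > 2)
      stop("binary exposure must take at most two distinct values")
    mask <- outer(D, D, "==") * 1
    KD <- K * mask
  } else {
    if (is.null(distance)) {
      rng <- diff(range(D))
      if (rng == 0) rng <- 1  # constant exposure: everyone fully shared
      distance <- function(x, y) abs(x - y) / rng
    }
    dmat <- outer(D, D, distance)
    if (any(dmat < -1e-12) || any(dmat > 1 + 1e-12))
      stop("exposure distance must map into [0, 1]")
    KD <- K * (1 - pmin(pmax(dmat, 0), 1))
  }
  KD <- (KD + t(KD)) / 2
  new("KinshipPair", K = K, KD = KD, exposure = as.numeric(D),
      exposureKind = kind)
}

#' Ridge stabilization of a kinship matrix
#'
#' Replaces `K` by `K + eps * I` so that the combined random-effect
#' covariance is positive definite. With `onlyIfNeeded = TRUE` (default)
#' the shift is applied only when the smallest eigenvalue of `K` falls at
#' or below `threshold`.
#'
#' @param K symmetric matrix.
#' @param eps positive ridge (default 1e-4).
#' @param onlyIfNeeded apply the shift only for numerically singular `K`.
#' @param threshold smallest-eigenvalue cutoff under the policy
#'   (default 1e-8).
#' @return Stabilized symmetric matrix.
#' @export
stabilizePSD <- function(K, eps = 1e-4, onlyIfNeeded = TRUE,
                         threshold = 1e-8) {
  if (eps <= 0) stop("eps must be positive")
  K <- as.matrix(K)
  if (onlyIfNeeded) {
    emin <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
    if (emin > threshold) return(K)
  }
  K + diag(eps, nrow(K))
}

#' Spectral decomposition of the random-effect covariance
#'
#' Eigendecomposition `U diag(evalues) U'` of `tau_g K + tau_d K_D`, the
#' covariance of the combined polygenic and polygenic-by-environment random
#' effect. Performed once per variance-component estimate; the inverse
#' `U diag(1/evalues) U'` is then reused along the whole regularization
#' path.
#'
#' @param tauG,tauD non-negative variance components, not both zero.
#' @param K kinship matrix.
#' @param KD gene-by-environment kinship (or `NULL` / ignored when
#'   `tauD = 0`).
#' @return A [SpectralBasis-class].
#' @export
spectralDecompose <- function(tauG, tauD = 0, K, KD = NULL) {
  if (tauG < 0 || tauD < 0 || tauG + tauD <= 0)
    stop("need tauG >= 0, tauD >= 0 and tauG + tauD > 0")
  Sigma <- tauG * K
  if (tauD > 0) {
    if (is.null(KD)) stop("tauD > 0 requires KD")
    Sigma <- Sigma + tauD * KD
  }
  e <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  if (min(e$values) <= 0)
    stop("combined covariance is not positive definite; ",
         "increase the stabilization ridge (see stabilizePSD)")
  new("SpectralBasis", U = e$vectors, evalues = e$values,
      tau = c(g = tauG, d = tauD))
}

## inverse covariance from a spectral basis
basisInverse <- function(basis)
  eigenVectors(basis) %*% (t(eigenVectors(basis)) / eigenValues(basis))
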