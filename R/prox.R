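#' Proximal operator of the sparse group lasso penalty
#'
#' Closed-form proximal map of
#' `t * [(1 - rho) * lambda * ||(beta_j, gamma_j)||_2 + rho * lambda * |gamma_j|]`
#' for a single SNP group: soft-threshold the interaction coordinate at
#' `t * rho * lambda`, then shrink the pair as a group at
#' `t * (1 - rho) * lambda`. The composition is exact for this composite
#' penalty and is what enforces strong hierarchy: the interaction
#' coefficient can survive only when the group as a whole survives, and the
#' extra L1 pressure on it means the main effect can be selected alone.
#'
#' @param uBeta,uGamma input coordinates (vectors of equal length are
#'   processed elementwise).
#' @param t positive step size.
#' @param lambda overall penalty level (>= 0).
#' @param rho GEI-sparsity mixing parameter in [0, 1).
#' @return A list with vectors `beta` and `gamma`.
#' @examples
#' proxSparseGroup(1, 1, t = 1, lambda = 1, rho = 0.5)
#' @export
proxSparseGroup <- function(uBeta, uGamma, t, lambda, rho) {
  stopifnot(t > 0, lambda >= 0, rho >= 0, rho < 1,
            length(uBeta) == length(uGamma))
  out <- vapply(seq_along(uBeta), function(i)
    .proxPairCpp(uBeta[i], uGamma[i], t, lambda, rho), numeric(2))
  list(beta = out[1, ], gamma = out[2, ])
}

#' Smallest penalty with an empty model
#'
#' Computes `lambda_max`, the smallest `lambda` at which the null-covariate
#' solution (all penalized coefficients zero) satisfies the sparse group
#' lasso subgradient conditions
#' `||(grad_beta_j, soft(grad_gamma_j, rho * lambda))||_2 <= (1 - rho) * lambda`
#' for every group j. At `rho = 0` this is the closed form
#' `max_j ||(grad_beta_j, grad_gamma_j)||_2`; for `rho > 0` the per-group
#' crossing point is found by bisection.
#'
#' @param gradBeta,gradGamma absolute quasi-score components per SNP,
#'   evaluated at the null-covariate fit.
#' @param rho mixing parameter in [0, 1).
#' @return Scalar `lambda_max` (0, with a warning, when all gradients
#'   vanish).
#' @export
computeLambdaMax <- function(gradBeta, gradGamma = NULL, rho = 0) {
  gb <- abs(gradBeta)
  gg <- if (is.null(gradGamma)) numeric(length(gb)) else abs(gradGamma)
  stopifnot(length(gb) == length(gg), rho >= 0, rho < 1)
  nrm <- sqrt(gb^2 + gg^2)
  if (all(nrm == 0)) {
    warning("all penalized gradients are zero; lambda_max = 0")
    return(0)
  }
  if (rho == 0) return(max(nrm))
  lo <- rep(0, length(gb))
  hi <- nrm / (1 - rho)
  for (it in 1:100) {
    mid <- (lo + hi) / 2
    s <- pmax(gg - rho * mid, 0)
    over <- sqrt(gb^2 + s^2) > (1 - rho) * mid
    lo[over] <- mid[over]
    hi[!over] <- mid[!over]
  }
  max(hi)
}

## TRUE for path points where a gamma is active without its beta
violatesHierarchy <- function(beta, gamma) {
  bz <- as.matrix(beta != 0)
  gz <- as.matrix(gamma != 0)
  as.logical(colSums(gz & !bz) > 0)
}
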