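#' Plain logistic lasso baseline
#'
#' Benchmark comparator: an ordinary (unstructured) logistic lasso on the
#' standardized genotypes, with optional unpenalized covariates, fitted by
#' glmnet. Population structure is not modelled; callers typically add
#' leading kinship eigenvectors to `Z` for a PC-adjusted baseline. This is
#' a convenience for side-by-side benchmarking, not part of the
#' mixed-model method.
#'
#' @param y binary response.
#' @param Z optional unpenalized covariates.
#' @param G standardized genotype matrix (penalized).
#' @param lambda optional lambda sequence (on the objective scale of
#'   [fitPath()], i.e. summed, not averaged, log-likelihood; divided by n
#'   internally for glmnet).
#' @param ... passed to `glmnet::glmnet`.
#' @return The glmnet fit object.
#' @export
lassoBaseline <- function(y, Z = NULL, G, lambda = NULL, ...) {
  if (!requireNamespace("glmnet", quietly = TRUE))
    stop("the lasso baseline requires the glmnet package")
  X <- cbind(Z, G)
  pf <- c(rep(0, if (is.null(Z)) 0 else ncol(Z)), rep(1, ncol(G)))
  glmnet::glmnet(X, y, family = "binomial", standardize = FALSE,
                 penalty.factor = pf,
                 lambda = if (!is.null(lambda)) lambda / length(y),
                 ...)
}
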