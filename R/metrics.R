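#' Selection-performance metrics
#'
#' Compares an estimated support (indices of non-zero coefficients) with
#' the true causal set among `p` predictors:
#' `FPR = |est \ true| / (p - |true|)`, `TPR = |est & true| / |true|`,
#' `FDR = |est \ true| / |est|` (0 for an empty model: no discoveries, no
#' false discoveries), `precision = 1 - FDR`, and the F1 score
#' `2 (1 / precision + 1 / TPR)^-1`, the harmonic mean of precision and
#' recall, set to 0 when either is 0.
#'
#' @param estimated integer indices of selected predictors.
#' @param truth integer indices of causal predictors (non-empty).
#' @param p total number of predictors (> `length(truth)`).
#' @return One-row `data.frame` with `modelSize`, `FPR`, `TPR`, `FDR`,
#'   `precision`, `F1`.
#' @examples
#' selectionMetrics(c(1, 3), c(1, 2), p = 5)
#' @export
selectionMetrics <- function(estimated, truth, p) {
  estimated <- unique(as.integer(estimated))
  truth <- unique(as.integer(truth))
  if (length(truth) == 0) stop("TPR undefined: empty true support")
  if (p <= length(truth)) stop("FPR undefined: no non-causal predictors")
  if (length(estimated) && (any(estimated < 1) || any(estimated > p)))
    stop("estimated support outside 1..p")
  tp <- length(intersect(estimated, truth))
  fp <- length(setdiff(estimated, truth))
  fpr <- fp / (p - length(truth))
  tpr <- tp / length(truth)
  fdr <- if (length(estimated)) fp / length(estimated) else 0
  prec <- 1 - fdr
  f1 <- if (tpr > 0 && prec > 0) 2 / (1 / prec + 1 / tpr) else 0
  data.frame(modelSize = length(estimated), FPR = fpr, TPR = tpr,
             FDR = fdr, precision = prec, F1 = f1)
}

#' Selection metrics of a path point against simulated truth
#'
#' Convenience wrapper evaluating main-effect and GEI selection separately
#' for one point of a [PathFit-class] against a [SimulatedData-class].
#'
#' @param fit a [PathFit-class].
#' @param point path point index.
#' @param truthData a [SimulatedData-class].
#' @return Two-row `data.frame` (effect = "main", "gei").
#' @export
pathPointMetrics <- function(fit, point, truthData) {
  cs <- coef(fit, point)
  p <- length(cs$beta)
  rbind(
    cbind(effect = "main",
          selectionMetrics(which(cs$beta != 0), truthData@causalMain, p)),
    cbind(effect = "gei",
          selectionMetrics(which(cs$gamma != 0), truthData@causalGEI, p)))
}
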