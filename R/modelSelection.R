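#' Area under the ROC curve
#'
#' Mann-Whitney concordance probability: the probability that a randomly
#' chosen case scores higher than a randomly chosen control, ties counted
#' one half. Invariant to strictly increasing transformations of the
#' scores.
#'
#' @param scores numeric risk scores.
#' @param labels binary labels in {0, 1}, both classes present.
#' @return Scalar in [0, 1].
#' @examples
#' aucScore(c(0.9, 0.4, 0.6), c(1, 1, 0))  # 0.5
#' @export
aucScore <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined with a single class")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validate the penalty grid
#'
#' K-fold cross-validation of the `(lambda, rho)` grid. Variance
#' components and the per-rho lambda grids are estimated once on the full
#' data (the two-step philosophy: the null model is not refit per fold);
#' each fold refits the regularization path on its training portion, with
#' the random-effect covariance restricted to the training block and
#' re-decomposed, and scores the held-out samples with fixed effects only
#' (optionally adding the kinship-transferred random effect). Folds are
#' stratified by case status for the binomial family.
#'
#' @param y,Z,D,G as in [fitPath()].
#' @param kinship a [KinshipPair-class] or single kinship matrix; must
#'   match what was used for `nullFit`.
#' @param nullFit a [NullFit-class] from [fitNull()] on the full data.
#' @param family a [FamilySpec-class].
#' @param folds number of folds (>= 2, default 10).
#' @param metric `"deviance"` (mean binomial deviance, minimized) or
#'   `"auc"` (maximized).
#' @param rhoGrid,nLambda,lambdaMinRatio grid controls, see [fitPath()].
#' @param seed integer seed making folds and the whole surface
#'   reproducible.
#' @param transferRandomEffects use the conditional-mean kinship transfer
#'   when scoring held-out samples (default `FALSE`: fixed effects only).
#' @param oneSE select the sparsest (largest lambda) model within one
#'   standard error of the optimum instead of the optimum itself.
#' @param control see [pathControl()].
#' @return A [CVFit-class]. Ties in the metric are broken toward larger
#'   lambda, then smaller rho.
#' @export
crossValidate <- function(y, Z = NULL, D, G, kinship, nullFit,
                          family = binomialFamily(), folds = 10L,
                          metric = c("deviance", "auc"),
                          rhoGrid = seq(0, 0.9, length.out = 10),
                          nLambda = 50L, lambdaMinRatio = 0.01,
                          seed = 1L, transferRandomEffects = FALSE,
                          oneSE = FALSE, control = pathControl()) {
  metric <- match.arg(metric)
  n <- length(y)
  stopifnot(folds >= 2)
  K <- if (is(kinship, "KinshipPair")) kinshipMatrix(kinship) else
         as.matrix(kinship)
  KD <- if (is(kinship, "KinshipPair")) gxeKinshipMatrix(kinship) else NULL
  tau <- nullFit@tau
  tauG <- unname(tau["g"])
  tauD <- if ("d" %in% names(tau)) unname(tau["d"]) else 0

  ## full-data basis, path and per-rho lambda grids
  fullBasis <- makeBasis(tauG, tauD, K, KD)
  fam <- nullFit@family
  fullFit <- fitPath(y, Z = Z, D = D, G = G, basis = fullBasis,
                     family = fam, rhoGrid = rhoGrid, nLambda = nLambda,
                     lambdaMinRatio = lambdaMinRatio, control = control)
  nRho <- length(rhoGrid)
  lambdaGrid <- matrix(fullFit@lambda, nrow = nLambda, ncol = nRho)

  foldIds <- stratifiedFolds(y, folds, seed,
                             stratify = fam@name == "binomial")

  surface <- array(NA_real_, dim = c(nLambda, nRho, folds))
  for (f in seq_len(folds)) {
    tr <- which(foldIds != f)
    va <- which(foldIds == f)
    if (fam@name == "binomial" &&
        (length(unique(y[va])) < 2) && metric == "auc")
      stop("fold ", f, " holds a single class; AUC undefined")
    basisTr <- makeBasis(tauG, tauD, K[tr, tr],
                         if (!is.null(KD)) KD[tr, tr] else NULL)
    fitTr <- fitPath(y[tr], Z = Z[tr, , drop = FALSE], D = D[tr],
                     G = G[tr, , drop = FALSE], basis = basisTr,
                     family = fam, rhoGrid = rhoGrid,
                     lambdaGrid = lambdaGrid, control = control)
    for (ptIdx in seq_along(fitTr@lambda)) {
      cs <- coef(fitTr, ptIdx)
      bNew <- if (transferRandomEffects)
        transferB(tauG, tauD, K, KD, tr, va, fitTr@b[, ptIdx]) else 0
      etaVa <- linearPredictor(cs, Z[va, , drop = FALSE], D[va],
                               G[va, , drop = FALSE]) + bNew
      muVa <- famLinkinv(fam, etaVa)
      li <- (ptIdx - 1L) %% nLambda + 1L
      ri <- (ptIdx - 1L) %/% nLambda + 1L
      surface[li, ri, f] <- if (metric == "deviance")
        mean(famDevianceResiduals(fam, y[va], muVa))
      else aucScore(etaVa, y[va])
    }
  }

  metricMean <- apply(surface, c(1, 2), mean)
  metricSE <- apply(surface, c(1, 2), stats::sd) / sqrt(folds)
  better <- if (metric == "deviance") metricMean else -metricMean
  best <- which(better == min(better), arr.ind = TRUE)
  ## ties: larger lambda (smaller row index), then smaller rho
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  li <- best[1]; ri <- best[2]
  if (oneSE) {
    thr <- better[li, ri] + metricSE[li, ri]
    ok <- which(better <= thr, arr.ind = TRUE)
    ok <- ok[order(ok[, 1], ok[, 2]), , drop = FALSE][1, ]
    li <- ok[1]; ri <- ok[2]
  }
  bestIndex <- as.integer((ri - 1L) * nLambda + li)

  new("CVFit", metric = metric, metricMean = metricMean,
      metricSE = metricSE, lambdaGrid = lambdaGrid,
      rhoGrid = rhoGrid, lambdaBest = lambdaGrid[li, ri],
      rhoBest = rhoGrid[ri], foldIds = as.integer(foldIds),
      fit = fullFit, bestIndex = bestIndex)
}

makeBasis <- function(tauG, tauD, K, KD) {
  if (tauG + tauD <= 1e-10) return(NULL)
  if (tauD <= 1e-10) spectralDecompose(max(tauG, 1e-10), 0, K)
  else spectralDecompose(tauG, tauD, K, KD)
}

stratifiedFolds <- function(y, folds, seed, stratify = TRUE) {
  n <- length(y)
  ids <- integer(n)
  withSeed(seed, {
    if (stratify) {
      for (cl in unique(y)) {
        idx <- which(y == cl)
        ids[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
    } else {
      ids <- sample(rep_len(seq_len(folds), n))
    }
  })
  ids
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
             globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  eval.parent(substitute(expr))
}

linearPredictor <- function(cs, Z, D, G) {
  eta <- rep(cs$theta[1], nrow(G))
  if (!is.null(Z) && ncol(Z) > 0)
    eta <- eta + as.numeric(as.matrix(Z) %*% cs$theta[-1])
  if (!is.null(D) && length(D) && !is.na(cs$alpha))
    eta <- eta + cs$alpha * as.numeric(D)
  act <- which(cs$beta != 0 | cs$gamma != 0)
  if (length(act)) {
    eta <- eta + as.numeric(G[, act, drop = FALSE] %*% cs$beta[act])
    if (!is.null(D) && any(cs$gamma != 0))
      eta <- eta + as.numeric((G[, act, drop = FALSE] * as.numeric(D)) %*%
                                cs$gamma[act])
  }
  eta
}

## conditional-mean transfer of random effects to new samples:
## b_new = Sigma[new, train] Sigma[train, train]^-1 b_train
transferB <- function(tauG, tauD, K, KD, tr, va, bTrain) {
  Sct <- tauG * K[va, tr, drop = FALSE]
  Stt <- tauG * K[tr, tr, drop = FALSE]
  if (tauD > 0 && !is.null(KD)) {
    Sct <- Sct + tauD * KD[va, tr, drop = FALSE]
    Stt <- Stt + tauD * KD[tr, tr, drop = FALSE]
  }
  if (tauG + tauD <= 1e-10) return(rep(0, length(va)))
  diag(Stt) <- diag(Stt) + 1e-8
  as.numeric(Sct %*% solve(Stt, bTrain))
}

#' Predict case probabilities for new subjects
#'
#' Forms `eta = Z theta + D alpha + G beta + (D * G) gamma + b_new` and
#' applies the inverse link. New genotypes must be standardized with the
#' training MAFs. When cross-kinship blocks are supplied, the random
#' effect is transferred by its conditional Gaussian mean
#' `b_new = Sigma[new, train] Sigma[train, train]^-1 b_train`; otherwise
#' `b_new = 0`.
#'
#' @param coefs coefficient list as returned by `coef()` on a
#'   [PathFit-class] or [CVFit-class].
#' @param nullFit the training [NullFit-class] (variance components and
#'   random effects for the transfer term).
#' @param newZ,newD,newG covariates, exposure and standardized genotypes of
#'   the new subjects.
#' @param Kcross optional new x train kinship block (same SNP set as the
#'   training kinship).
#' @param Ktrain train x train kinship (required with `Kcross`).
#' @param trainExposure training exposure vector (required with `Kcross`
#'   when the null model had a gene-by-environment component).
#' @param family a [FamilySpec-class].
#' @return Vector of probabilities (binomial) or means (gaussian).
#' @export
predictProbabilities <- function(coefs, nullFit, newZ = NULL, newD, newG,
                                 Kcross = NULL, Ktrain = NULL,
                                 trainExposure = NULL,
                                 family = nullFit@family) {
  p <- length(coefs$beta)
  if (ncol(newG) != p)
    stop("newG has ", ncol(newG), " columns but the model has ", p,
         " SNP groups")
  eta <- linearPredictor(coefs, newZ, newD, newG)
  if (!is.null(Kcross)) {
    if (is.null(Ktrain)) stop("Kcross requires Ktrain")
    tau <- nullFit@tau
    tauG <- unname(tau["g"])
    tauD <- if ("d" %in% names(tau)) unname(tau["d"]) else 0
    Sct <- tauG * Kcross
    Stt <- tauG * Ktrain
    if (tauD > 0) {
      if (is.null(trainExposure))
        stop("gene-by-environment transfer needs trainExposure")
      maskCT <- outer(as.numeric(newD), as.numeric(trainExposure), "==") * 1
      maskTT <- outer(as.numeric(trainExposure),
                      as.numeric(trainExposure), "==") * 1
      Sct <- Sct + tauD * (Kcross * maskCT)
      Stt <- Stt + tauD * (Ktrain * maskTT)
    }
    if (tauG + tauD > 1e-10) {
      diag(Stt) <- diag(Stt) + 1e-8
      eta <- eta + as.numeric(Sct %*% solve(Stt, nullFit@b))
    }
  }
  famLinkinv(family, eta)
}
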