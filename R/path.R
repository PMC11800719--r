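#' Control parameters for the path algorithm
#'
#' @param innerTol maximum absolute coefficient change declaring the inner
#'   block coordinate descent converged.
#' @param innerMaxIter cap on inner coordinate-descent cycles per proximal
#'   Newton step.
#' @param outerTol relative objective change declaring a path point
#'   converged.
#' @param outerMaxIter cap on outer (weights refresh) iterations per path
#'   point.
#' @param nullTol,nullMaxIter tolerances for the null-covariate fit used to
#'   anchor each rho sweep and compute lambda_max.
#' @param halvings maximum step-halvings when an outer step increases the
#'   objective.
#' @return A named list.
#' @export
pathControl <- function(innerTol = 1e-7, innerMaxIter = 100L,
                        outerTol = 1e-6, outerMaxIter = 50L,
                        nullTol = 1e-8, nullMaxIter = 100L,
                        halvings = 10L) {
  list(innerTol = innerTol, innerMaxIter = as.integer(innerMaxIter),
       outerTol = outerTol, outerMaxIter = as.integer(outerMaxIter),
       nullTol = nullTol, nullMaxIter = as.integer(nullMaxIter),
       halvings = as.integer(halvings))
}

#' Penalized objective value
#'
#' Evaluates `Q_lambda = -sum_i ql_i + b' Sigma^-1 b / 2 +
#' (1 - rho) lambda sum_j ||(beta_j, gamma_j)||_2 + rho lambda sum_j
#' |gamma_j|`, the regularized PQL working objective at the current
#' coefficients and rotated random effects.
#'
#' @param y response vector.
#' @param eta linear predictor including the random-effect contribution.
#' @param b random-effect vector (`Sigma^-1 b` supplied via `SigmaInvB` or
#'   computed from `SigmaInv`).
#' @param beta,gamma penalized coefficient vectors.
#' @param lambda,rho penalty parameters.
#' @param family a [FamilySpec-class].
#' @param SigmaInv inverse random-effect covariance (`NULL` for a model
#'   without random effects).
#' @param SigmaInvB optional precomputed `Sigma^-1 b`.
#' @return Scalar objective value.
#' @export
objectiveValue <- function(y, eta, b, beta, gamma, lambda, rho, family,
                           SigmaInv = NULL, SigmaInvB = NULL) {
  f <- sum(famNegQL(family, y, eta))
  if (!is.null(SigmaInv) || !is.null(SigmaInvB)) {
    if (is.null(SigmaInvB)) SigmaInvB <- as.numeric(SigmaInv %*% b)
    f <- f + 0.5 * sum(b * SigmaInvB)
  }
  f + penaltyValue(beta, gamma, lambda, rho)
}

penaltyValue <- function(beta, gamma, lambda, rho) {
  if (lambda == 0) return(0)
  lambda * ((1 - rho) * sum(sqrt(beta^2 + gamma^2)) + rho * sum(abs(gamma)))
}

#' Generalized ridge update of the rotated random effects
#'
#' Holding the fixed effects fixed, the rotated random effects
#' `delta = U' b` minimize the weighted least-squares criterion with
#' `Lambda^-1` as ridge matrix: `(U' W U + Lambda^-1) delta = U' W r`,
#' where `r` is the working residual excluding the random-effect
#' contribution. Decreases the working objective at fixed coefficients.
#'
#' @param residual working residual `z - eta_fixed` (length n).
#' @param w working weights.
#' @param basis a [SpectralBasis-class].
#' @return List with `delta` (rotated) and `b = U delta`.
#' @export
updateRandomEffects <- function(residual, w, basis) {
  U <- eigenVectors(basis)
  A <- crossprod(U * sqrt(w)) + diag(1 / eigenValues(basis),
                                     length(eigenValues(basis)))
  delta <- solve(A, crossprod(U, w * residual))
  list(delta = as.numeric(delta), b = as.numeric(U %*% delta))
}

## b-space equivalent used internally: (diag(w) + Sigma^-1) b = w * residual
updateRandomEffectsB <- function(residual, w, SigmaInv) {
  M <- SigmaInv
  diag(M) <- diag(M) + w
  R <- chol(M)
  as.numeric(backsolve(R, forwardsolve(t(R), w * residual)))
}

## Null-covariate PQL fit at fixed variance components: beta = gamma = 0,
## (theta, alpha, b) iterated to convergence. Anchors each rho sweep and
## the lambda_max computation.
nullCovariateFit <- function(y, Xu, family, SigmaInv, control) {
  n <- length(y)
  q <- ncol(Xu)
  th <- qr.solve(Xu, if (family@name == "binomial")
                       qlogis(pmin(pmax(rep(mean(y), n), 0.05), 0.95))
                     else y)
  b <- numeric(n)
  eta <- as.numeric(Xu %*% th) + b
  for (it in seq_len(control$nullMaxIter)) {
    mu <- famLinkinv(family, eta)
    if (family@name == "binomial") mu <- pmin(pmax(mu, 1e-8), 1 - 1e-8)
    w <- workingWeights(mu, family, phi = if (family@name == "gaussian")
                                             family@phi else 1)
    z <- workingResponse(family, y, eta, mu)
    if (!is.null(SigmaInv)) {
      b <- updateRandomEffectsB(z - as.numeric(Xu %*% th), w, SigmaInv)
    }
    r <- z - b
    XtW <- t(Xu * w)
    th <- solve(XtW %*% Xu, XtW %*% r)
    etaNew <- as.numeric(Xu %*% th) + b
    if (max(abs(etaNew - eta)) < control$nullTol * (1 + max(abs(eta)))) {
      eta <- etaNew
      break
    }
    eta <- etaNew
  }
  mu <- famLinkinv(family, eta)
  if (family@name == "binomial") mu <- pmin(pmax(mu, 1e-8), 1 - 1e-8)
  list(theta = as.numeric(th), b = b, eta = eta, mu = mu)
}

#' Fit the sparse group lasso regularization path
#'
#' Minimizes the regularized PQL working objective over a two-dimensional
#' `(lambda, rho)` grid with a proximal Newton outer loop (weights frozen
#' within each step) and block coordinate descent over SNP groups
#' `(beta_j, gamma_j)`. Each rho sweep starts from the null-covariate fit
#' at its own `lambda_max` (no penalized coefficient selected) and warm
#' starts across decreasing lambda; within every outer iteration the
#' rotated random effects are refreshed by a generalized ridge solve. The
#' covariate effects and the exposure main effect are never penalized, and
#' strong hierarchy (`gamma_j != 0` only when `beta_j != 0`) holds at every
#' path point by construction. `rho = 0` is the pure group lasso.
#'
#' @param y response vector.
#' @param Z optional covariate matrix (intercept added internally).
#' @param D exposure vector (`NULL` for a model without exposure, in which
#'   case interactions are disabled).
#' @param G n x p matrix of standardized genotypes.
#' @param basis [SpectralBasis-class] from [spectralDecompose()], or `NULL`
#'   for a model without random effects.
#' @param family a [FamilySpec-class].
#' @param rhoGrid vector of GEI-sparsity parameters in [0, 1); default 10
#'   values evenly spaced on [0, 0.9].
#' @param nLambda number of lambda values per rho (default 50).
#' @param lambdaMinRatio `lambda_min / lambda_max` (default 0.01); the grid
#'   is equally spaced on the log10 scale.
#' @param lambdaGrid optional nLambda x nRho matrix of lambda values
#'   overriding the data-derived grids (used to align cross-validation
#'   folds).
#' @param interactions set `FALSE` to drop all GEI columns (main-effects
#'   lasso/group path).
#' @param control see [pathControl()].
#' @return A [PathFit-class]; points are ordered by rho sweep, then
#'   decreasing lambda.
#' @export
fitPath <- function(y, Z = NULL, D = NULL, G, basis = NULL,
                    family = binomialFamily(),
                    rhoGrid = seq(0, 0.9, length.out = 10),
                    nLambda = 50L, lambdaMinRatio = 0.01,
                    lambdaGrid = NULL, interactions = !is.null(D),
                    control = pathControl()) {
  n <- length(y)
  G <- as.matrix(G)
  p <- ncol(G)
  stopifnot(nrow(G) == n, all(rhoGrid >= 0), all(rhoGrid < 1))
  if (interactions && is.null(D))
    stop("interactions require an exposure vector D")
  Xu <- cbind(`(Intercept)` = rep(1, n), Z)
  if (!is.null(D)) Xu <- cbind(Xu, D = as.numeric(D))
  q <- ncol(Xu)
  Dvec <- if (interactions) as.numeric(D) else numeric(n)
  phi <- if (family@name == "gaussian") {
    if (is.na(family@phi)) stop("gaussian family needs phi (fit the null first)")
    family@phi
  } else 1

  SigmaInv <- if (!is.null(basis)) basisInverse(basis) else NULL

  nullFitCov <- nullCovariateFit(y, Xu, family, SigmaInv, control)

  nRho <- length(rhoGrid)
  if (!is.null(lambdaGrid)) {
    stopifnot(ncol(lambdaGrid) == nRho)
    nLambda <- nrow(lambdaGrid)
  }
  npts <- nRho * as.integer(nLambda)

  betaM <- matrix(0, p, npts)
  gammaM <- matrix(0, p, npts)
  thetaM <- matrix(0, q, npts)
  bM <- matrix(0, n, npts)
  lambdaV <- rhoV <- objV <- numeric(npts)
  sizeB <- sizeG <- iterV <- integer(npts)
  convV <- logical(npts)
  lambdaMaxV <- numeric(nRho)

  ## quasi-score at the null-covariate fit (canonical link)
  gscore <- (y - nullFitCov$mu) / phi
  gradB <- abs(as.numeric(crossprod(G, gscore)))
  gradG <- if (interactions) abs(as.numeric(crossprod(G, Dvec * gscore)))
           else numeric(p)

  pt <- 0L
  for (ri in seq_len(nRho)) {
    rho <- rhoGrid[ri]
    lmax <- computeLambdaMax(gradB, gradG, rho)
    lambdaMaxV[ri] <- lmax
    lambdas <- if (!is.null(lambdaGrid)) lambdaGrid[, ri]
               else 10^seq(log10(lmax), log10(lmax * lambdaMinRatio),
                           length.out = nLambda)

    ## each rho sweep starts independently from the null-covariate fit
    st <- list(theta = nullFitCov$theta, beta = numeric(p),
               gamma = numeric(p), b = nullFitCov$b, eta = nullFitCov$eta)

    for (li in seq_along(lambdas)) {
      lambda <- lambdas[li]
      st <- fitPathPoint(y, Xu, G, Dvec, st, lambda, rho, family, phi,
                         SigmaInv, interactions, control)
      pt <- pt + 1L
      betaM[, pt] <- st$beta
      gammaM[, pt] <- st$gamma
      thetaM[, pt] <- st$theta
      bM[, pt] <- st$b
      lambdaV[pt] <- lambda
      rhoV[pt] <- rho
      objV[pt] <- st$objective
      sizeB[pt] <- sum(st$beta != 0)
      sizeG[pt] <- sum(st$gamma != 0)
      iterV[pt] <- st$iterations
      convV[pt] <- st$converged
    }
  }

  alphaV <- if (!is.null(D)) thetaM[q, ] else rep(NA_real_, npts)
  thetaOut <- if (!is.null(D)) thetaM[-q, , drop = FALSE] else thetaM
  names(lambdaMaxV) <- format(rhoGrid)
  fam <- family
  fam@phi <- phi
  new("PathFit",
      lambda = lambdaV, rho = rhoV, lambdaMax = lambdaMaxV,
      beta = Matrix(betaM, sparse = TRUE),
      gamma = Matrix(gammaM, sparse = TRUE),
      theta = thetaOut, alpha = alphaV, b = bM,
      objective = objV, sizeMain = sizeB, sizeGEI = sizeG,
      iterations = iterV, converged = convV,
      snpIds = colnames(G) %||% paste0("snp", seq_len(p)),
      family = fam)
}

## Sparse-group KKT screen: indices of zero groups whose subgradient
## condition ||(gb_j, soft(gg_j, rho lambda))||_2 <= (1 - rho) lambda
## fails for the supplied per-group gradients.
kktViolators <- function(gb, gg, lambda, rho, active) {
  sg <- pmax(abs(gg) - rho * lambda, 0)
  setdiff(which(sqrt(gb^2 + sg^2) > (1 - rho) * lambda * (1 + 1e-10)),
          active)
}

## One path point: proximal Newton outer loop with step-halving and
## frozen weights inside each block-coordinate-descent call. The descent
## runs on an ever-active group set; after the outer loop converges, one
## exact-score gradient pass verifies the sparse-group KKT condition for
## every left-out group, admits violators and resumes (glmnet-style
## active-set strategy).
fitPathPoint <- function(y, Xu, G, D, st, lambda, rho, family, phi,
                         SigmaInv, useGEI, control) {
  n <- length(y)
  obj <- function(eta, b, beta, gamma, SigmaInvB = NULL)
    objectiveValue(y, eta, b, beta, gamma, lambda, rho, family,
                   SigmaInv = SigmaInv, SigmaInvB = SigmaInvB)

  eta <- st$eta
  theta <- st$theta; beta <- st$beta; gamma <- st$gamma; b <- st$b
  Qold <- obj(eta, b, beta, gamma)
  converged <- FALSE
  active <- which(beta != 0 | gamma != 0)
  totalIt <- 0L

  for (round in 1:20) {
    converged <- FALSE
    for (it in seq_len(control$outerMaxIter)) {
      mu <- famLinkinv(family, eta)
      if (family@name == "binomial") mu <- pmin(pmax(mu, 1e-8), 1 - 1e-8)
      w <- workingWeights(mu, family, phi = phi)
      z <- workingResponse(family, y, eta, mu)

      etaFixed <- eta - b
      bNew <- if (!is.null(SigmaInv))
        updateRandomEffectsB(z - etaFixed, w, SigmaInv) else b
      r <- z - etaFixed - bNew

      if (round == 1 && it == 1) {
        ## admit the groups this lambda step activates before descending
        wr <- w * r
        gb <- as.numeric(crossprod(G, wr))
        gg <- if (useGEI) as.numeric(crossprod(G, D * wr)) else 0 * gb
        active <- union(active, kktViolators(gb, gg, lambda, rho, active))
      }

      ## early weight refreshes tolerate a looser inner solve; the solve
      ## at the iteration where convergence can be declared always runs
      ## at the full inner tolerance
      tolIt <- if (it == 1) max(control$innerTol, 1e-4)
               else if (it == 2) max(control$innerTol, 1e-6)
               else control$innerTol
      cd <- .bcdInnerCpp(Xu, G, D, w, r, theta, beta, gamma,
                         as.integer(active - 1L), lambda, rho,
                         tolIt, control$innerMaxIter, useGEI)
      totalIt <- totalIt + 1L
      thetaNew <- cd$theta; betaNew <- cd$beta; gammaNew <- cd$gamma
      etaNew <- z - cd$residual

      Qnew <- obj(etaNew, bNew, betaNew, gammaNew)
      if (Qnew > Qold + 1e-8 * (1 + abs(Qold))) {
        ## quadratic model diverged: halve the step toward the previous
        ## state
        s <- 1
        for (h in seq_len(control$halvings)) {
          s <- s / 2
          thetaNew <- theta + s * (cd$theta - theta)
          betaNew <- beta + s * (cd$beta - beta)
          gammaNew <- gamma + s * (cd$gamma - gamma)
          bNew2 <- b + s * (bNew - b)
          etaNew <- eta + s * ((z - cd$residual) - eta)
          Qnew <- obj(etaNew, bNew2, betaNew, gammaNew)
          if (Qnew <= Qold + 1e-8 * (1 + abs(Qold))) { bNew <- bNew2; break }
        }
        if (Qnew > Qold + 1e-8 * (1 + abs(Qold))) {
          ## still increasing: keep the previous iterate, flag the point
          return(list(theta = theta, beta = beta, gamma = gamma, b = b,
                      eta = eta, objective = Qold, iterations = totalIt,
                      converged = FALSE))
        }
      }
      theta <- thetaNew; beta <- betaNew; gamma <- gammaNew
      b <- bNew; eta <- etaNew
      if (tolIt <= control$innerTol &&
          abs(Qold - Qnew) <= control$outerTol * (1 + abs(Qnew))) {
        Qold <- Qnew
        converged <- TRUE
        break
      }
      Qold <- Qnew
    }
    if (!converged) break
    ## exact-score KKT verification over all left-out groups
    mu <- famLinkinv(family, eta)
    if (family@name == "binomial") mu <- pmin(pmax(mu, 1e-8), 1 - 1e-8)
    score <- (y - mu) / phi
    gb <- as.numeric(crossprod(G, score))
    gg <- if (useGEI) as.numeric(crossprod(G, D * score)) else 0 * gb
    viol <- kktViolators(gb, gg, lambda, rho,
                         union(active, which(beta != 0 | gamma != 0)))
    if (!length(viol)) break
    active <- union(active, viol)
  }
  list(theta = theta, beta = beta, gamma = gamma, b = b, eta = eta,
       objective = Qold, iterations = totalIt, converged = converged)
}
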