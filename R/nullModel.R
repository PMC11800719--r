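#' Null-model variance component estimation (PQL + AI-REML)
#'
#' Two-step strategy, step one: with all genetic fixed effects set to zero,
#' estimate the covariate effects, the exposure effect, the variance
#' components `(tau_g, tau_d)` of the polygenic and polygenic-by-environment
#' random effects, the dispersion (gaussian only) and the predicted random
#' effects. The algorithm alternates (a) the PQL working linear mixed model
#' for the fixed effects and BLUP given the current weights, and (b) one
#' average-information REML update of the variance parameters on the
#' working response, with step-halving on the REML objective and truncation
#' of negative components at the zero boundary.
#'
#' The working model uses response `z = eta + (y - mu) g'(mu)` and
#' covariance `V = W^-1 + tau_g K + tau_d K_D` (binomial; for gaussian the
#' dispersion enters as an additional `phi * I` component). The REML score
#' for component k is `(z' P K_k P z - tr(P K_k)) / 2` and the average
#' information is `z' P K_k P K_l P z / 2`, with
#' `P = V^-1 - V^-1 X (X' V^-1 X)^-1 X' V^-1`.
#'
#' @param y response vector (binary in {0, 1} for binomial).
#' @param Z optional n x m covariate matrix (no intercept column; one is
#'   added).
#' @param D optional exposure vector, entering as an unpenalized fixed
#'   effect.
#' @param kinship a [KinshipPair-class] (two random effects) or a single
#'   kinship matrix (one random effect).
#' @param family a [FamilySpec-class]; see [binomialFamily()].
#' @param priorWeights known prior weights `a_i`.
#' @param control list overriding `tolerance` (relative parameter change,
#'   default 1e-4), `maxIter` (default 50), `scoreTolerance` (REML score
#'   per observation, default 1e-3).
#' @return A [NullFit-class].
#' @seealso [spectralDecompose()], [fitPath()]
#' @export
fitNull <- function(y, Z = NULL, D = NULL, kinship, family = binomialFamily(),
                    priorWeights = 1, control = list()) {
  ctrl <- modifyList(list(tolerance = 1e-4, maxIter = 50L,
                          scoreTolerance = 1e-3), control)
  n <- length(y)
  if (family@name == "binomial" && !all(y %in% c(0, 1)))
    stop("binomial family requires a binary 0/1 response")
  a <- rep_len(priorWeights, n)

  if (is(kinship, "KinshipPair")) {
    kernels <- list(g = kinshipMatrix(kinship), d = gxeKinshipMatrix(kinship))
  } else {
    kernels <- list(g = as.matrix(kinship))
  }
  stopifnot(all(vapply(kernels, nrow, 0L) == n))

  X <- cbind(`(Intercept)` = rep(1, n), Z)
  if (!is.null(D)) X <- cbind(X, D = as.numeric(D))
  if (qr(X)$rank < ncol(X))
    stop("collinear fixed-effect columns in [Z, D]")
  m <- ncol(X)
  if (n < m + 2) stop("need n >= m + 2 observations")

  gaussian <- family@name == "gaussian"

  ## fixed-effects-only start
  eta <- if (gaussian) rep(mean(y), n) else rep(qlogis(pmin(pmax(mean(y),
                                                0.05), 0.95)), n)
  fit0 <- stats::glm.fit(X, y, weights = a,
                         family = if (gaussian) stats::gaussian()
                                  else stats::binomial())
  eta <- as.numeric(X %*% fit0$coefficients)
  mu <- famLinkinv(family, eta)
  if (family@name == "binomial") mu <- pmin(pmax(mu, 1e-6), 1 - 1e-6)

  w <- workingWeights(mu, family, a, phi = 1)
  z <- workingResponse(family, y, eta, mu)
  v0 <- stats::var(z - as.numeric(X %*% fit0$coefficients))
  theta <- c(phi = if (gaussian) 0.5 * v0 else NA_real_,
             vapply(kernels, function(k) 0.1 * v0, 0))
  theta <- theta[!is.na(theta)]

  ## kernel list including the dispersion kernel for gaussian
  vkern <- c(if (gaussian) list(phi = diag(1 / a, n)), kernels)

  converged <- FALSE
  scores <- rep(NA_real_, length(theta))
  b <- numeric(n)
  for (iter in seq_len(ctrl$maxIter)) {
    w <- workingWeights(mu, family, a, phi = 1)
    z <- workingResponse(family, y, eta, mu)
    V0 <- if (gaussian) matrix(0, n, n) else diag(1 / w, n)

    up <- airemlStep(z, X, V0, vkern, theta)
    delta <- abs(up$theta - theta) / pmax(abs(theta), 1e-4)
    theta <- up$theta
    scores <- up$scores / n

    ## refresh the working fit at the updated variance parameters
    V <- V0
    for (k in seq_along(vkern)) V <- V + theta[k] * vkern[[k]]
    Vi <- cholInverse(V)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    thetaF <- solve(XtViX, crossprod(ViX, z))
    Pz <- Vi %*% (z - X %*% thetaF)
    Sb <- matrix(0, n, 1)
    for (k in names(kernels)) Sb <- Sb + theta[k] * (kernels[[k]] %*% Pz)
    b <- as.numeric(Sb)
    eta <- as.numeric(X %*% thetaF + b)
    mu <- famLinkinv(family, eta)
    if (family@name == "binomial") mu <- pmin(pmax(mu, 1e-6), 1 - 1e-6)

    atBoundary <- theta < 1e-10
    if (max(delta) < ctrl$tolerance &&
        all(abs(scores) < ctrl$scoreTolerance | atBoundary)) {
      converged <- TRUE
      break
    }
  }

  tau <- theta[names(kernels)]
  phi <- if (gaussian) unname(theta["phi"]) else 1
  fam <- family
  fam@phi <- phi
  coefs <- as.numeric(thetaF)
  names(coefs) <- colnames(X)
  alpha <- if (!is.null(D)) unname(coefs["D"]) else NA_real_
  thetaOut <- if (!is.null(D)) coefs[setdiff(names(coefs), "D")] else coefs

  new("NullFit", theta = thetaOut, alpha = alpha, tau = tau, phi = phi,
      b = b, eta = eta, mu = mu, scores = scores,
      converged = converged, nIter = iter, family = fam)
}

## symmetric positive definite inverse via Cholesky
cholInverse <- function(V) {
  R <- chol(V)
  chol2inv(R)
}

## One AI-REML update of the variance parameters theta for the working
## linear mixed model z ~ X beta + sum_k theta_k Kernel_k, V0 a fixed
## covariance offset. Uses tr(A B) = sum(A * B) for symmetric matrices, so
## each iteration costs one Cholesky inversion plus O(n^2) work per kernel.
airemlStep <- function(z, X, V0, kernels, theta, ridge = 1e-8) {
  n <- length(z)
  K <- length(kernels)
  buildV <- function(th) {
    V <- V0
    for (k in seq_len(K)) V <- V + th[k] * kernels[[k]]
    V
  }
  remlParts <- function(th) {
    V <- buildV(th)
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    Vi <- chol2inv(R)
    ViX <- Vi %*% X
    XtViX <- crossprod(X, ViX)
    thetaF <- solve(XtViX, crossprod(ViX, z))
    resid <- z - X %*% thetaF
    Pz <- Vi %*% resid
    ll <- -0.5 * (2 * sum(log(diag(R))) +
                  determinant(XtViX, logarithm = TRUE)$modulus +
                  sum(resid * Pz))
    list(Vi = Vi, ViX = ViX, XtViX = XtViX, Pz = Pz, ll = as.numeric(ll))
  }
  cur <- remlParts(theta)
  if (is.null(cur)) stop("working covariance not positive definite")

  applyP <- function(v) {
    as.numeric(cur$Vi %*% v -
               cur$ViX %*% solve(cur$XtViX, crossprod(cur$ViX, v)))
  }
  KPz <- lapply(kernels, function(Kk) as.numeric(Kk %*% cur$Pz))
  PKPz <- lapply(KPz, applyP)
  score <- numeric(K)
  AI <- matrix(0, K, K)
  for (k in seq_len(K)) {
    Kk <- kernels[[k]]
    trViK <- sum(cur$Vi * Kk)
    M <- crossprod(cur$ViX, Kk %*% cur$ViX)
    trPK <- trViK - sum(diag(solve(cur$XtViX, M)))
    score[k] <- 0.5 * (sum(cur$Pz * KPz[[k]]) - trPK)
    for (l in k:K) {
      AI[k, l] <- AI[l, k] <- 0.5 * sum(KPz[[k]] * PKPz[[l]])
    }
  }

  ## components pinned at the zero boundary with a negative score are
  ## fixed there and removed from the AI system, so they cannot tilt the
  ## update direction of the interior components
  active <- theta > 1e-10 | score > 0
  step <- numeric(K)
  if (any(active)) {
    Aact <- AI[active, active, drop = FALSE]
    step[active] <- tryCatch(
      solve(Aact + diag(ridge * max(diag(Aact), 1), sum(active)),
            score[active]),
      error = function(e) score[active] / max(diag(Aact), 1))
  }
  tryStep <- function(direction) {
    s <- 1
    for (h in 1:12) {
      cand <- pmax(theta + s * direction, 0)
      parts <- remlParts(cand)
      if (!is.null(parts) && parts$ll >= cur$ll - 1e-8)
        return(list(theta = cand, scores = score, ll = parts$ll))
      s <- s / 2
    }
    NULL
  }
  out <- tryStep(step)
  if (is.null(out)) {
    ## AI direction failed: fall back to a scaled-gradient step
    grad <- ifelse(active, score / pmax(diag(AI), 1), 0)
    out <- tryStep(grad)
  }
  if (is.null(out)) out <- list(theta = theta, scores = score, ll = cur$ll)
  out
}
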