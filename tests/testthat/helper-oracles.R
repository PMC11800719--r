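## Independent numeric minimizer of the scalar-group prox problem
##   0.5 ((x1 - u1)^2 + (x2 - u2)^2) +
##   t [(1 - rho) lambda ||x||_2 + rho lambda |x2|]
## by nested golden-section search (convex in each coordinate, solution
## bracketed between 0 and u).
numericProxOracle <- function(u1, u2, t, lambda, rho) {
  h <- function(x1, x2)
    0.5 * ((x1 - u1)^2 + (x2 - u2)^2) +
      t * ((1 - rho) * lambda * sqrt(x1^2 + x2^2) + rho * lambda * abs(x2))
  inner <- function(x2) {
    lo <- min(0, u1); hi <- max(0, u1)
    if (lo == hi) return(list(val = h(u1, x2), x1 = u1))
    o <- optimize(function(x1) h(x1, x2), c(lo, hi), tol = 1e-12)
    list(val = o$objective, x1 = o$minimum)
  }
  lo <- min(0, u2); hi <- max(0, u2)
  if (lo == hi) {
    res <- inner(u2)
    return(c(res$x1, u2))
  }
  o <- optimize(function(x2) inner(x2)$val, c(lo, hi), tol = 1e-12)
  c(inner(o$minimum)$x1, o$minimum)
}

## Exact subgradient check of the sparse group lasso stationarity
## conditions at a fitted path point, using the exact quasi-score at the
## final state (not the frozen quadratic). Returns the largest violation.
kktViolation <- function(y, Xu, G, GD, D, cs, b, lambda, rho, SigmaInv,
                         family = binomialFamily()) {
  p <- length(cs$beta)
  theta <- c(cs$theta, if (!is.na(cs$alpha)) cs$alpha)
  eta <- as.numeric(Xu %*% theta) +
    as.numeric(G %*% cs$beta) + as.numeric(GD %*% cs$gamma) + b
  mu <- hierGxE:::famLinkinv(family, eta)
  score <- (y - mu) / family@phi
  viol <- max(abs(crossprod(Xu, score)))          # unpenalized block
  if (!is.null(SigmaInv))                         # random-effect block
    viol <- max(viol, max(abs(score - SigmaInv %*% b)))
  gB <- -as.numeric(crossprod(G, score))
  gG <- -as.numeric(crossprod(GD, score))
  for (j in seq_len(p)) {
    bj <- cs$beta[j]; gj <- cs$gamma[j]
    if (bj == 0 && gj == 0) {
      s <- max(abs(gG[j]) - rho * lambda, 0)
      viol <- max(viol, sqrt(gB[j]^2 + s^2) - (1 - rho) * lambda)
    } else {
      nrm <- sqrt(bj^2 + gj^2)
      viol <- max(viol, abs(gB[j] + (1 - rho) * lambda * bj / nrm))
      if (gj != 0) {
        viol <- max(viol, abs(gG[j] + (1 - rho) * lambda * gj / nrm +
                                rho * lambda * sign(gj)))
      } else {
        viol <- max(viol, abs(gG[j]) - rho * lambda)
      }
    }
  }
  viol
}

## Block-exchangeable kinship: nBlocks families of blockSize exchangeable
## members (within-block coefficient `within`), a simple strongly
## structured relatedness pattern.
makeBlockKinship <- function(nBlocks, blockSize, within = 1) {
  n <- nBlocks * blockSize
  K <- matrix(0, n, n)
  for (b in seq_len(nBlocks)) {
    idx <- ((b - 1) * blockSize + 1):(b * blockSize)
    K[idx, idx] <- within
  }
  diag(K) <- 1
  K
}

## Binary-trait data under the null (no genetic fixed effects):
## logit(mu) = theta0 + alpha D + b, b ~ N(0, tauG K + tauD K_D)
simulateNullBinary <- function(K, KD, tauG, tauD, theta0 = -0.5,
                               alpha = 0.25, D = NULL) {
  n <- nrow(K)
  if (is.null(D)) D <- rbinom(n, 1, 0.5)
  b <- simulateRandomEffect(K, KD, tauG, tauD, sigma2 = 1)
  eta <- theta0 + alpha * D + b
  list(y = rbinom(n, 1, plogis(eta)), D = D, b = b)
}

## Small structured dataset for fitting tests
smallSimData <- function(n = 200, p = 60, seed = 42, ...) {
  simulateGxEData(simulationConfig(n = n, p = p, nCausalMain = 8,
                                   nCausalGEI = 4, kinshipSnps = 300,
                                   seed = seed, ...))
}
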