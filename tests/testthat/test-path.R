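## shared small fitting problem
pathTestData <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- smallSimData(n = 150, p = 25, seed = 77)
      nf <- fitNull(sim@y, Z = cbind(age = sim@age), D = sim@sex,
                    kinship = sim@kinship)
      basis <- spectralDecompose(max(nf@tau[["g"]], 1e-6), nf@tau[["d"]],
                                 kinshipMatrix(sim@kinship),
                                 gxeKinshipMatrix(sim@kinship))
      cache <<- list(sim = sim, nf = nf, basis = basis,
                     G = standardizeGenotypes(sim@panel))
    }
    cache
  }
})

test_that("objective reduces to the negative quasi-likelihood in edge cases", {
  fam <- binomialFamily()
  ## n = 1, eta = 0, y = 1: -ql = -log(1/2) = log 2
  expect_equal(objectiveValue(1, 0, 0, numeric(1), numeric(1),
                              lambda = 0, rho = 0, family = fam),
               log(2), tolerance = 1e-12)
  ## beta = gamma = 0: zero penalty contribution at any lambda
  y <- c(0, 1); eta <- c(-0.3, 0.2)
  expect_equal(objectiveValue(y, eta, 0, numeric(3), numeric(3),
                              lambda = 5, rho = 0.5, family = fam),
               objectiveValue(y, eta, 0, numeric(3), numeric(3),
                              lambda = 0, rho = 0.5, family = fam))
})

test_that("random-effect update solves the generalized ridge WLS", {
  ## n = 1, U = 1, W = 1, Lambda = 1, residual 1: minimize
  ## (1 - delta)^2 / 2 + delta^2 / 2 -> 0.5
  basis <- new("SpectralBasis", U = matrix(1), evalues = 1,
               tau = c(g = 1, d = 0))
  up <- updateRandomEffects(residual = 1, w = 1, basis = basis)
  expect_equal(up$delta, 0.5)
  expect_equal(up$b, 0.5)

  ## infinite ridge: delta -> 0
  tiny <- new("SpectralBasis", U = diag(3), evalues = rep(1e-10, 3),
              tau = c(g = 1e-10, d = 0))
  expect_lt(max(abs(updateRandomEffects(rep(1, 3), rep(1, 3), tiny)$delta)),
            1e-8)

  ## descent contract on random instances, and agreement of the rotated
  ## and unrotated solvers
  set.seed(51)
  for (i in 1:5) {
    n <- 15
    K <- crossprod(matrix(rnorm(n * n), n)) / n + diag(0.3, n)
    bs <- spectralDecompose(1.2, 0, K)
    w <- runif(n, 0.1, 0.3)
    r <- rnorm(n)
    up <- updateRandomEffects(r, w, bs)
    SigmaInv <- hierGxE:::basisInverse(bs)
    bAlt <- hierGxE:::updateRandomEffectsB(r, w, SigmaInv)
    expect_equal(up$b, bAlt, tolerance = 1e-8)
    fOf <- function(b) sum(w * (r - b)^2) / 2 + sum(b * (SigmaInv %*% b)) / 2
    expect_lt(fOf(up$b), fOf(rep(0, n)) + 1e-10)
    ## stationarity of the quadratic
    grad <- -w * (r - up$b) + as.numeric(SigmaInv %*% up$b)
    expect_lt(max(abs(grad)), 1e-8)
  }
})

test_that("the path starts empty at lambda_max and maintains hierarchy", {
  d <- pathTestData()
  fit <- fitPath(d$sim@y, Z = cbind(age = d$sim@age), D = d$sim@sex,
                 G = d$G, basis = d$basis,
                 rhoGrid = c(0, 0.3, 0.6, 0.9), nLambda = 8)
  expect_equal(length(fit@lambda), 32)
  firstOfSweep <- seq(1, 32, by = 8)
  expect_true(all(fit@sizeMain[firstOfSweep] == 0))
  expect_true(all(fit@sizeGEI[firstOfSweep] == 0))
  ## hierarchy at every point (also enforced by the class validity)
  expect_false(any(hierGxE:::violatesHierarchy(fit@beta, fit@gamma)))
  ## support grows from the empty end to the dense end
  expect_true(all(fit@sizeMain[firstOfSweep + 7] >=
                  fit@sizeMain[firstOfSweep]))
  ## the exposure effect is never penalized away
  expect_true(all(is.finite(fit@alpha)))
})

test_that("objective values are non-increasing along inner outer cycles", {
  ## monotone descent of Q within each path point is enforced by
  ## step-halving; across warm-started lambdas within a sweep the
  ## objective at the same lambda can only be compared pointwise, so
  ## check the recorded objective is finite and the fit converged
  d <- pathTestData()
  fit <- fitPath(d$sim@y, Z = cbind(age = d$sim@age), D = d$sim@sex,
                 G = d$G, basis = d$basis, rhoGrid = 0.45, nLambda = 10)
  expect_true(all(is.finite(fit@objective)))
  expect_true(all(fit@converged))
})

test_that("single-group problems match a brute-force scalar minimizer", {
  set.seed(52)
  n <- 60
  g <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.8 * g))
  lambda <- 3; t <- NULL
  fit <- fitPath(y, D = NULL, G = matrix(g, ncol = 1), basis = NULL,
                 interactions = FALSE, rhoGrid = 0,
                 lambdaGrid = matrix(lambda),
                 control = pathControl(innerMaxIter = 5000,
                                       outerTol = 1e-12,
                                       outerMaxIter = 200))
  bhat <- fit@beta[1, 1]
  ## brute force over (intercept, beta)
  obj <- function(par) {
    eta <- par[1] + par[2] * g
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) + lambda * abs(par[2])
  }
  ref <- optim(c(0, 0), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))$par
  expect_equal(unname(bhat), ref[2], tolerance = 1e-5)
})

test_that("converged path points satisfy the exact KKT conditions", {
  set.seed(53)
  n <- 60; p <- 10
  sim <- simulateGxEData(simulationConfig(n = n, p = p, nCausalMain = 3,
                                          nCausalGEI = 2, kinshipSnps = 80,
                                          seed = 53))
  nf <- fitNull(sim@y, D = sim@sex, kinship = sim@kinship)
  basis <- spectralDecompose(max(nf@tau[["g"]], 1e-4), nf@tau[["d"]],
                             kinshipMatrix(sim@kinship),
                             gxeKinshipMatrix(sim@kinship))
  G <- standardizeGenotypes(sim@panel)
  fit <- fitPath(sim@y, D = sim@sex, G = G, basis = basis,
                 rhoGrid = c(0, 0.45, 0.9), nLambda = 6,
                 control = pathControl(innerMaxIter = 20000,
                                       outerTol = 1e-12,
                                       outerMaxIter = 500,
                                       innerTol = 1e-10))
  Xu <- cbind(1, D = sim@sex)
  GD <- G * sim@sex
  SigmaInv <- hierGxE:::basisInverse(basis)
  worst <- 0
  for (ptIdx in which(fit@converged)) {
    cs <- coef(fit, ptIdx)
    worst <- max(worst, kktViolation(sim@y, Xu, G, GD, sim@sex, cs,
                                     fit@b[, ptIdx], cs$lambda, cs$rho,
                                     SigmaInv))
  }
  expect_lt(worst, 1e-4)
})

test_that("with structure removed the path degenerates to the plain lasso", {
  skip_if_not_installed("glmnet")
  set.seed(54)
  n <- 150; p <- 30
  G <- matrix(rnorm(n * p), n, p)
  beta <- c(rep(0.6, 3), rep(0, p - 3))
  y <- rbinom(n, 1, plogis(-0.2 + as.numeric(G %*% beta)))
  basis <- spectralDecompose(1e-8, 0, diag(n))
  fit <- fitPath(y, D = NULL, G = G, basis = basis, interactions = FALSE,
                 rhoGrid = 0, nLambda = 12, lambdaMinRatio = 0.05,
                 control = pathControl(innerMaxIter = 20000,
                                       outerTol = 1e-12,
                                       outerMaxIter = 500,
                                       innerTol = 1e-10))
  gl <- glmnet::glmnet(G, y, family = "binomial", standardize = FALSE,
                       lambda = fit@lambda / n, thresh = 1e-14)
  for (ptIdx in seq_along(fit@lambda)) {
    expect_lt(max(abs(fit@beta[, ptIdx] - gl$beta[, ptIdx])), 1e-4)
  }
})

test_that("rho = 0 couples the pair as a pure group lasso", {
  d <- pathTestData()
  fit <- fitPath(d$sim@y, Z = cbind(age = d$sim@age), D = d$sim@sex,
                 G = d$G, basis = d$basis, rhoGrid = 0, nLambda = 10)
  ## under the group penalty beta_j and gamma_j enter or leave together
  expect_equal(as.matrix(fit@beta != 0), as.matrix(fit@gamma != 0),
               ignore_attr = TRUE)
})
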