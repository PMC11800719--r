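test_that("AUC equals the Mann-Whitney concordance with ties at one half", {
  expect_equal(aucScore(c(0.9, 0.4, 0.6), c(1, 1, 0)), 0.5)
  expect_equal(aucScore(1:10, c(rep(0, 5), rep(1, 5))), 1)
  expect_equal(aucScore(rep(0.3, 8), rep(c(0, 1), 4)), 0.5)
  expect_error(aucScore(1:3, c(1, 1, 1)), "single class")

  ## invariance under strictly increasing transforms
  set.seed(61)
  s <- rnorm(50); l <- rbinom(50, 1, 0.5)
  expect_equal(aucScore(s, l), aucScore(exp(s), l))
  expect_equal(aucScore(s, l), aucScore(rank(s), l))
})

test_that("probability prediction composes fixed effects and kinship transfer", {
  nf <- new("NullFit", theta = c(`(Intercept)` = 0), alpha = 0,
            tau = c(g = 1, d = 0), phi = 1, b = 0.8, eta = 0, mu = 0.5,
            scores = 0, converged = TRUE, nIter = 1L,
            family = binomialFamily())
  coefs <- list(theta = 0, alpha = 0, beta = numeric(3), gamma = numeric(3))
  G <- matrix(0, 2, 3)
  ## empty support, no transfer: probability one half everywhere
  expect_equal(predictProbabilities(coefs, nf, newD = c(0, 1), newG = G),
               rep(0.5, 2))
  ## zero cross-kinship block: identical to fixed-effects-only
  expect_equal(predictProbabilities(coefs, nf, newD = c(0, 1), newG = G,
                                    Kcross = matrix(0, 2, 1),
                                    Ktrain = matrix(1)),
               rep(0.5, 2))
  ## conditional-mean transfer: b_new = 0.5 * 1^-1 * 0.8 = 0.4
  pr <- predictProbabilities(coefs, nf, newD = 0, newG = matrix(0, 1, 3),
                             Kcross = matrix(0.5), Ktrain = matrix(1))
  expect_equal(qlogis(pr), 0.4, tolerance = 1e-6)
  expect_error(predictProbabilities(coefs, nf, newD = 0,
                                    newG = matrix(0, 1, 5)),
               "SNP groups")
})

test_that("cross-validation is reproducible and selects the surface optimum", {
  sim <- smallSimData(n = 160, p = 30, seed = 71)
  Gs <- standardizeGenotypes(sim@panel)
  Z <- cbind(age = sim@age)
  nf <- fitNull(sim@y, Z = Z, D = sim@sex, kinship = sim@kinship)
  cv1 <- crossValidate(sim@y, Z = Z, D = sim@sex, G = Gs,
                       kinship = sim@kinship, nullFit = nf, folds = 3,
                       rhoGrid = c(0, 0.45, 0.9), nLambda = 6, seed = 5)
  cv2 <- crossValidate(sim@y, Z = Z, D = sim@sex, G = Gs,
                       kinship = sim@kinship, nullFit = nf, folds = 3,
                       rhoGrid = c(0, 0.45, 0.9), nLambda = 6, seed = 5)
  expect_identical(cv1@foldIds, cv2@foldIds)
  expect_equal(cv1@metricMean, cv2@metricMean)
  expect_identical(c(cv1@lambdaBest, cv1@rhoBest),
                   c(cv2@lambdaBest, cv2@rhoBest))

  expect_equal(dim(cv1@metricMean), c(6, 3))
  li <- (cv1@bestIndex - 1L) %% 6L + 1L
  ri <- (cv1@bestIndex - 1L) %/% 6L + 1L
  expect_equal(cv1@metricMean[li, ri], min(cv1@metricMean))
  expect_equal(cv1@lambdaBest, cv1@lambdaGrid[li, ri])
  expect_equal(cv1@rhoBest, cv1@rhoGrid[ri])

  ## folds partition the samples and are stratified by case status
  expect_setequal(unique(cv1@foldIds), 1:3)
  caseCounts <- table(cv1@foldIds[sim@y == 1])
  expect_lt(max(caseCounts) - min(caseCounts), 3)
})

test_that("the empty-model column of the CV surface is rho-invariant", {
  sim <- smallSimData(n = 140, p = 20, seed = 72)
  Gs <- standardizeGenotypes(sim@panel)
  nf <- fitNull(sim@y, D = sim@sex, kinship = sim@kinship)
  cv <- crossValidate(sim@y, D = sim@sex, G = Gs, kinship = sim@kinship,
                      nullFit = nf, folds = 3, rhoGrid = c(0, 0.3, 0.6),
                      nLambda = 4, seed = 2)
  ## at lambda_max every rho sweep fits the same covariate-only model, so
  ## the validation deviance in the first surface row must agree
  expect_lt(diff(range(cv@metricMean[1, ])), 1e-6)
})

test_that("the one-standard-error rule never selects a denser model", {
  sim <- smallSimData(n = 140, p = 20, seed = 73)
  Gs <- standardizeGenotypes(sim@panel)
  nf <- fitNull(sim@y, D = sim@sex, kinship = sim@kinship)
  args <- list(sim@y, D = sim@sex, G = Gs, kinship = sim@kinship,
               nullFit = nf, folds = 3, rhoGrid = c(0, 0.45),
               nLambda = 5, seed = 3)
  cv <- do.call(crossValidate, args)
  cv1se <- do.call(crossValidate, c(args, oneSE = TRUE))
  expect_gte(cv1se@lambdaBest, cv@lambdaBest)
})
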