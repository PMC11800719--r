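test_that("structured genotype panels are deterministic and polymorphic", {
  set.seed(1); a <- simulateStructuredGenotypes(80, 60, nPops = 3, Fst = 0.2)
  set.seed(1); b <- simulateStructuredGenotypes(80, 60, nPops = 3, Fst = 0.2)
  expect_identical(genotypes(a$panel), genotypes(b$panel))
  expect_identical(a$population, b$population)
  expect_true(all(maf(a$panel) > 0 & maf(a$panel) < 1))
  expect_error(simulateStructuredGenotypes(10, 5, Fst = 0), "Fst")
})

test_that("population structure shows up in the leading GRM eigenvector", {
  set.seed(2)
  rs <- replicate(10, {
    g <- simulateStructuredGenotypes(500, 2000, nPops = 2, Fst = 0.2,
                                     popWeights = c(0.5, 0.5))
    K <- computeGRM(standardizeGenotypes(g$panel))
    ev <- eigen(K, symmetric = TRUE)
    abs(cor(ev$vectors[, 1], g$population))
  })
  expect_gt(mean(rs), 0.9)

  ## near-zero drift: the leading eigenvalue gap collapses
  set.seed(3)
  gapAt <- function(f) {
    g <- simulateStructuredGenotypes(300, 800, nPops = 2, Fst = f,
                                     popWeights = c(0.5, 0.5))
    ev <- eigen(computeGRM(standardizeGenotypes(g$panel)),
                symmetric = TRUE, only.values = TRUE)$values
    ev[1] - ev[2]
  }
  expect_gt(gapAt(0.2) / gapAt(1e-4), 10)
})

test_that("causal architecture counts match the two scenarios", {
  cfgH <- simulationConfig(n = 50, p = 400, seed = 4, kinshipSnps = 50,
                           nCausalMain = 100, nCausalGEI = 50)
  set.seed(4)
  effH <- drawEffects(cfgH)
  expect_length(union(effH$S, effH$Sprime), 100)   # S' inside S
  expect_true(all(effH$Sprime %in% effH$S))
  expect_equal(sum(effH$beta != 0), 100)
  expect_equal(sum(effH$gamma != 0), 50)

  cfgN <- simulationConfig(n = 50, p = 400, seed = 4, kinshipSnps = 50,
                           hierarchy = FALSE)
  set.seed(4)
  effN <- drawEffects(cfgN)
  expect_length(union(effN$S, effN$Sprime), 150)   # disjoint by draw
  expect_length(intersect(effN$S, effN$Sprime), 0)

  expect_error(simulationConfig(nCausalMain = 10, nCausalGEI = 20),
               "\\|S'\\| <= \\|S\\|")
})

test_that("effect sizes have the stated per-SNP variance", {
  cfg <- simulationConfig(n = 50, p = 200, nCausalMain = 100,
                          nCausalGEI = 50, kinshipSnps = 50, sigma2 = 9)
  set.seed(5)
  draws <- replicate(1000, drawEffects(cfg)$beta)
  bet <- draws[draws != 0]
  ## Var(beta_j) = h2Main sigma2 / |S| = 0.2 * 9 / 100 = 0.018
  se <- sqrt(2 / length(bet)) * 0.018
  expect_lt(abs(var(bet) - 0.018), 3 * se)
})

test_that("random-effect draws have the prescribed covariance", {
  expect_identical(simulateRandomEffect(diag(5), NULL, 0, 0), rep(0, 5))

  set.seed(6)
  d <- replicate(10000, simulateRandomEffect(diag(3), NULL, 1))
  expect_lt(max(abs(apply(d, 1, var) - 1)), 3 * sqrt(2 / 10000))

  set.seed(7)
  n <- 20
  K <- makeBlockKinship(4, 5, within = 0.6)
  D <- rbinom(n, 1, 0.5)
  KD <- gxeKinshipMatrix(buildGxEKinship(K, D, "binary"))
  draws <- replicate(5000, simulateRandomEffect(K, KD, 0.7, 0.4))
  emp <- tcrossprod(draws) / 5000
  target <- 0.7 * K + 0.4 * KD
  ## each entry's MC standard error is about sqrt((s_ii s_jj + s_ij^2)/m)
  se <- sqrt((diag(target) %o% diag(target) + target^2) / 5000)
  expect_true(all(abs(emp - target) < 5 * se))

  expect_error(simulateRandomEffect(-diag(3), NULL, 1), "semi-definite")
})

test_that("phenotype model uses the stated covariate effects and intercepts", {
  n <- 2000
  Gstd <- matrix(0, n, 1)
  set.seed(8)
  ## no genetic effects: P(y = 1) = 0.5 at pi0 = 0.5, sex = age = 0
  ph <- simulatePhenotypes(Gstd, rep(1L, n), pi0 = 0.5, sex = rep(0, n),
                           age = rep(0, n), beta = 0, gamma = 0,
                           epsilon = rep(0, n))
  expect_true(all(ph$eta == 0))
  expect_lt(abs(mean(ph$y) - 0.5), 3 * sqrt(0.25 / n))

  ## sex and age enter with -log(1.3) and log(1.05) per 10 years
  ph2 <- simulatePhenotypes(Gstd, rep(1L, n), pi0 = 0.5, sex = rep(1, n),
                            age = rep(10, n), beta = 0, gamma = 0,
                            epsilon = rep(0, n))
  expect_equal(unique(ph2$eta), -log(1.3) + log(1.05))
  expect_error(simulatePhenotypes(Gstd, rep(3L, n), pi0 = 0.5,
                                  sex = rep(0, n), age = rep(0, n),
                                  beta = 0, gamma = 0,
                                  epsilon = rep(0, n)),
               "population")
})

test_that("full datasets are reproducible and respect the variance budget", {
  cfg <- simulationConfig(n = 400, p = 150, nCausalMain = 50,
                          nCausalGEI = 25, kinshipSnps = 200, seed = 9)
  s1 <- simulateGxEData(cfg)
  s2 <- simulateGxEData(cfg)
  expect_identical(genotypes(s1@panel), genotypes(s2@panel))
  expect_identical(s1@y, s2@y)
  expect_identical(s1@epsilon, s2@epsilon)

  ## kinship SNP set disjoint from candidates by construction
  expect_length(intersect(snpIds(s1@panel), paste0("kin", 1:200)), 0)

  ## empirical variance fractions of the fixed genetic components: each
  ## causal SNP contributes h2 sigma2 / |S| on average, inflated by the
  ## drift-induced excess variance of standardized columns under pooling
  ## (factor (1 + 0.625 F) / (1 - 0.188 F) for the default 7-population
  ## weights; see the methods vignette)
  infl <- (1 + 0.625 * cfg$Fst) / (1 - 0.188 * cfg$Fst)
  shares <- vapply(1:20, function(i) {
    s <- simulateGxEData(simulationConfig(n = 400, p = 150,
                                          nCausalMain = 50, nCausalGEI = 25,
                                          kinshipSnps = 60, seed = 100 + i))
    Gs <- standardizeGenotypes(s@panel)
    mean(vapply(s@causalMain,
                function(j) var(s@beta[j] * Gs[, j]), 0)) / s@config$sigma2
  }, 0)
  expectShare <- 0.2 / 50 * infl
  expect_equal(mean(shares), expectShare, tolerance = 0.1)
})
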