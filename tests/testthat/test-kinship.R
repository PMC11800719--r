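test_that("genotype standardization applies the HWE affine transform", {
  panel <- GenotypePanel(matrix(c(0, 1, 2), 3, 1), maf = 0.25)
  gt <- standardizeGenotypes(panel)
  expect_equal(as.numeric(gt), c(-0.8164966, 0.8164966, 2.4494897),
               tolerance = 1e-6)
  ## centered exactly at its mean when g = 2p
  panel2 <- GenotypePanel(matrix(1, 1, 1), maf = 0.5)
  expect_equal(as.numeric(standardizeGenotypes(panel2)), 0)
})

test_that("missing genotypes are imputed to the column mean and bad panels rejected", {
  g <- matrix(c(0, 1, NA, 2), 4, 1)
  gt <- standardizeGenotypes(GenotypePanel(g, maf = 0.25))
  expect_equal(gt[3, 1], 0)
  expect_error(GenotypePanel(matrix(c(0, 0, 0), 3, 1)), "monomorphic.*snp1")
  expect_error(GenotypePanel(matrix(c(0, 1, 3), 3, 1)), "0, 1, 2")
  expect_error(standardizeGenotypes(GenotypePanel(matrix(c(0, 1), 2, 1),
                                                  maf = 0.5)), NA)
})

test_that("GRM is the standardized cross-product with unit-scale diagonal", {
  Gt <- matrix(c(1, -1), 2, 1)
  expect_equal(computeGRM(Gt), matrix(c(1, -1, -1, 1), 2))
  expect_equal(computeGRM(matrix(0, 3, 4)), matrix(0, 3, 3))
  expect_error(computeGRM(matrix(0, 3, 0)), "zero columns")

  ## HWE genotypes: average diagonal near 1, exact symmetry
  set.seed(7)
  G <- matrix(rbinom(200 * 500, 2, 0.3), 200, 500)
  K <- computeGRM(standardizeGenotypes(GenotypePanel(G)))
  expect_identical(K, t(K))
  expect_equal(mean(diag(K)), 1, tolerance = 0.05)
})

test_that("GRM is invariant to SNP column order", {
  set.seed(8)
  G <- matrix(rbinom(50 * 100, 2, runif(100, 0.1, 0.5)), 50, 100,
              byrow = TRUE)
  panel <- GenotypePanel(G, dropMonomorphic = TRUE)
  K1 <- computeGRM(standardizeGenotypes(panel))
  perm <- sample(ncol(genotypes(panel)))
  panel2 <- GenotypePanel(genotypes(panel)[, perm], maf = maf(panel)[perm])
  K2 <- computeGRM(standardizeGenotypes(panel2))
  expect_lt(max(abs(K1 - K2)), 1e-12)
})

test_that("binary exposure masks kinship exactly", {
  K <- matrix(c(1, 0.5, 0.5, 1), 2)
  kp <- buildGxEKinship(K, c(1, 0), kind = "binary")
  expect_equal(gxeKinshipMatrix(kp), matrix(c(1, 0, 0, 1), 2))
  kp2 <- buildGxEKinship(K, c(1, 1), kind = "binary")
  expect_equal(gxeKinshipMatrix(kp2), K)

  ## property: same-exposure entries preserved, cross-exposure exactly 0
  set.seed(9)
  n <- 30
  Kr <- crossprod(matrix(rnorm(n * n), n)) / n
  D <- rbinom(n, 1, 0.5)
  KD <- gxeKinshipMatrix(buildGxEKinship(Kr, D, kind = "binary"))
  same <- outer(D, D, "==")
  expect_identical(KD[same], Kr[same])
  expect_true(all(KD[!same] == 0))
})

test_that("continuous exposure down-weights kinship by the distance", {
  K <- matrix(c(1, 0.8, 0.8, 1), 2)
  kp <- buildGxEKinship(K, c(0, 0.5), kind = "continuous",
                        distance = function(x, y) abs(x - y))
  expect_equal(gxeKinshipMatrix(kp), matrix(c(1, 0.4, 0.4, 1), 2))
  ## diagonal always preserved; default metric is range-normalized
  kp2 <- buildGxEKinship(K, c(2, 12), kind = "continuous")
  expect_equal(diag(gxeKinshipMatrix(kp2)), diag(K))
  expect_equal(gxeKinshipMatrix(kp2)[1, 2], 0)
  expect_error(buildGxEKinship(K, c(0, 3), kind = "continuous",
                               distance = function(x, y) abs(x - y)),
               "\\[0, 1\\]")
})

test_that("ridge stabilization shifts eigenvalues by exactly eps when needed", {
  expect_equal(stabilizePSD(matrix(0, 2, 2), eps = 1e-4),
               diag(1e-4, 2))
  K <- matrix(c(0.5, 0.5, 0.5, 0.5), 2)  # eigenvalues (1, 0)
  ev <- eigen(stabilizePSD(K, eps = 0.01), symmetric = TRUE)$values
  expect_equal(ev, c(1.01, 0.01))
  ## policy: an already-PD matrix is untouched
  expect_identical(stabilizePSD(diag(2), eps = 0.01), diag(2))
  expect_error(stabilizePSD(diag(2), eps = 0), "positive")
})

test_that("spectral decomposition reconstructs and inverts the covariance", {
  b <- spectralDecompose(1, 0, diag(3))
  expect_equal(eigenValues(b), rep(1, 3))
  b2 <- spectralDecompose(1, 0, matrix(c(2, 1, 1, 2), 2))
  expect_equal(eigenValues(b2), c(3, 1))

  set.seed(10)
  for (rep in 1:5) {
    n <- 20
    K <- crossprod(matrix(rnorm(n * n), n)) / n + diag(0.5, n)
    D <- rbinom(n, 1, 0.5)
    KD <- gxeKinshipMatrix(buildGxEKinship(K, D, "binary")) + diag(0.5, n)
    tg <- runif(1, 0.2, 2); td <- runif(1, 0.1, 1)
    bs <- spectralDecompose(tg, td, K, KD)
    U <- eigenVectors(bs)
    expect_lt(max(abs(crossprod(U) - diag(n))), 1e-10)
    Sigma <- tg * K + td * KD
    expect_lt(max(abs(U %*% (eigenValues(bs) * t(U)) - Sigma)), 1e-8)
    expect_lt(max(abs(hierGxE:::basisInverse(bs) %*% Sigma - diag(n))) /
                max(abs(Sigma)), 1e-8)
  }
  expect_error(spectralDecompose(0, 0, diag(2)), "tauG")
  expect_error(spectralDecompose(1, 0, -diag(2)), "positive definite")
})
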