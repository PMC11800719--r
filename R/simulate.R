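## Population weights mirroring the sample shares of a 7-population
## reference panel (African, Admixed American, Central/South Asian,
## East Asian, European, Middle Eastern, Oceanian).
defaultPopWeights <- c(0.24, 0.13, 0.19, 0.20, 0.19, 0.04, 0.01)

#' Simulation configuration
#'
#' Validated parameter list for the synthetic-data generator. Defaults are
#' the study design the generator emulates: n = 4097 samples in 7
#' populations, 10,000 candidate SNPs of which 100 carry main effects and
#' 50 carry gene-environment interaction (GEI) effects, main/GEI/polygenic/
#' polygenic-by-environment logit-scale variance fractions
#' (0.2, 0.1, 0.2, 0.1) at total variance sigma2 = 9 (the low-polygenic
#' setting; the high-polygenic setting uses (0.2, 0.1, 0.4, 0.2) with
#' sigma2 = 35), a hierarchical causal architecture, and a kinship matrix
#' built from a disjoint SNP set.
#'
#' @param n,p sample size and number of candidate SNPs.
#' @param nCausalMain,nCausalGEI sizes of the causal sets S and S'.
#' @param h2Main,h2GEI,h2G,h2D logit-scale variance fractions of the main,
#'   GEI, polygenic and polygenic-by-environment components (sum < 1).
#' @param sigma2 total logit-scale variance.
#' @param hierarchy draw S' as a subset of S (`TRUE`) or disjoint from S
#'   (`FALSE`).
#' @param nPops number of discrete populations.
#' @param popWeights population share vector (recycled/renormalized).
#' @param Fst Balding-Nichols drift parameter in (0, 0.5].
#' @param kinshipSnps SNPs used for the kinship matrix (disjoint from the
#'   candidates).
#' @param seed integer seed controlling the whole dataset.
#' @return Named list of validated parameters.
#' @export
simulationConfig <- function(n = 4097, p = 10000, nCausalMain = 100,
                             nCausalGEI = 50, h2Main = 0.2, h2GEI = 0.1,
                             h2G = 0.2, h2D = 0.1, sigma2 = 9,
                             hierarchy = TRUE, nPops = 7,
                             popWeights = defaultPopWeights, Fst = 0.1,
                             kinshipSnps = 5000, seed = 1L) {
  stopifnot(n >= 2, p >= 1, nCausalMain <= p, nCausalGEI <= p,
            h2Main >= 0, h2GEI >= 0, h2G >= 0, h2D >= 0,
            h2Main + h2GEI + h2G + h2D < 1,
            sigma2 > 0, nPops >= 1, Fst > 0, Fst <= 0.5)
  if (hierarchy && nCausalGEI > nCausalMain)
    stop("hierarchical architecture requires |S'| <= |S|")
  if (!hierarchy && nCausalMain + nCausalGEI > p)
    stop("disjoint causal sets need nCausalMain + nCausalGEI <= p")
  popWeights <- rep_len(popWeights, nPops)
  popWeights <- popWeights / sum(popWeights)
  list(n = n, p = p, nCausalMain = nCausalMain, nCausalGEI = nCausalGEI,
       h2Main = h2Main, h2GEI = h2GEI, h2G = h2G, h2D = h2D,
       sigma2 = sigma2, hierarchy = hierarchy, nPops = nPops,
       popWeights = popWeights, Fst = Fst, kinshipSnps = kinshipSnps,
       seed = as.integer(seed))
}

#' Structured genotypes under the Balding-Nichols model
#'
#' Draws ancestral allele frequencies `q_j ~ U(0.05, 0.5)`, population
#' frequencies `p_kj ~ Beta(q_j (1 - F) / F, (1 - q_j)(1 - F) / F)` and
#' genotypes `Binomial(2, p_kj)`, producing discrete populations separated
#' by drift. Columns that come out monomorphic in the sample are redrawn so
#' every SNP is polymorphic. Draws from the calling RNG state: seed outside
#' for reproducibility.
#'
#' @param n,p panel dimensions.
#' @param nPops number of populations.
#' @param Fst drift parameter in (0, 0.5].
#' @param popWeights population shares (renormalized; sizes are the
#'   largest-remainder rounding of `n * popWeights`).
#' @param population optional precomputed population labels (length n),
#'   e.g. to generate a second panel for the same samples.
#' @param idPrefix prefix for SNP identifiers.
#' @return List with `panel` ([GenotypePanel-class]) and `population`
#'   (integer labels).
#' @export
simulateStructuredGenotypes <- function(n, p, nPops = 7, Fst = 0.1,
                                        popWeights = defaultPopWeights,
                                        population = NULL,
                                        idPrefix = "snp") {
  if (Fst <= 0 || Fst > 0.5) stop("Fst must lie in (0, 0.5]")
  stopifnot(nPops >= 1)
  if (is.null(population)) {
    w <- rep_len(popWeights, nPops)
    w <- w / sum(w)
    sizes <- floor(n * w)
    rem <- n - sum(sizes)
    if (rem > 0) {
      frac <- n * w - sizes
      sizes[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
        sizes[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
    }
    population <- rep.int(seq_len(nPops), sizes)
  }
  stopifnot(length(population) == n)

  drawCols <- function(m) {
    q <- runif(m, 0.05, 0.5)
    shape <- (1 - Fst) / Fst
    freq <- matrix(rbeta(nPops * m, rep(q, each = nPops) * shape,
                         rep(1 - q, each = nPops) * shape),
                   nrow = nPops)
    G <- matrix(0L, n, m)
    for (k in seq_len(nPops)) {
      idx <- population == k
      if (!any(idx)) next
      G[idx, ] <- matrix(rbinom(sum(idx) * m, 2, rep(freq[k, ],
                                 each = sum(idx))), ncol = m)
    }
    G
  }
  G <- drawCols(p)
  for (attempt in 1:50) {
    mafHat <- colMeans(G) / 2
    mono <- mafHat <= 0 | mafHat >= 1
    if (!any(mono)) break
    G[, mono] <- drawCols(sum(mono))
  }
  panel <- GenotypePanel(G, snpIds = paste0(idPrefix, seq_len(p)))
  list(panel = panel, population = as.integer(population))
}

#' Draw sparse causal effects
#'
#' Samples the causal sets and effect sizes: `|S|` main effects
#' `beta_j ~ N(0, h2Main sigma2 / |S|)` and `|S'|` GEI effects
#' `gamma_j ~ N(0, h2GEI sigma2 / |S'|)`, so each causal SNP contributes an
#' equal expected share of the logit-scale variance. Under the
#' hierarchical architecture S' is drawn within S (total causal = |S|);
#' otherwise S' is drawn disjoint from S (total causal = |S| + |S'|).
#'
#' @param config a [simulationConfig()] list (fields p, nCausalMain,
#'   nCausalGEI, h2Main, h2GEI, sigma2, hierarchy).
#' @return List with vectors `beta`, `gamma` (length p) and index sets
#'   `S`, `Sprime`.
#' @export
drawEffects <- function(config) {
  p <- config$p
  S <- sort(sample.int(p, config$nCausalMain))
  Sprime <- if (config$hierarchy) {
    sort(sample(S, config$nCausalGEI))
  } else {
    sort(sample(setdiff(seq_len(p), S), config$nCausalGEI))
  }
  beta <- numeric(p)
  gamma <- numeric(p)
  beta[S] <- rnorm(length(S),
                   sd = sqrt(config$h2Main * config$sigma2 / length(S)))
  gamma[Sprime] <- rnorm(length(Sprime),
                         sd = sqrt(config$h2GEI * config$sigma2 /
                                   length(Sprime)))
  list(beta = beta, gamma = gamma, S = S, Sprime = Sprime)
}

#' Draw the two-component polygenic random effect
#'
#' One multivariate normal draw with covariance
#' `h2g sigma2 K + h2d sigma2 K_D`, via eigendecomposition of the combined
#' matrix (tiny negative eigenvalues from floating point are clipped at
#' zero; genuinely indefinite input is rejected).
#'
#' @param K,KD kinship and gene-by-environment kinship (`KD` may be `NULL`
#'   when `h2d = 0`).
#' @param h2g,h2d variance fractions (or absolute variances with
#'   `sigma2 = 1`).
#' @param sigma2 total variance scale.
#' @return Length-n random-effect vector (exact zero when both variance
#'   fractions are 0).
#' @export
simulateRandomEffect <- function(K, KD = NULL, h2g, h2d = 0, sigma2 = 1) {
  n <- nrow(K)
  if (h2g < 0 || h2d < 0) stop("variance fractions must be non-negative")
  if (h2g * sigma2 == 0 && h2d * sigma2 == 0) return(numeric(n))
  Sigma <- h2g * sigma2 * K
  if (h2d * sigma2 > 0) {
    if (is.null(KD)) stop("h2d > 0 requires KD")
    Sigma <- Sigma + h2d * sigma2 * KD
  }
  e <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(abs(e$values)))
    stop("combined random-effect covariance is not positive semi-definite")
  as.numeric(e$vectors %*% (sqrt(pmax(e$values, 0)) * rnorm(n)))
}

#' Simulate binary phenotypes from the logistic GEI model
#'
#' Generates `y_i ~ Bernoulli(expit(eta_i))` with
#' `eta = logit(pi0_k) - log(1.3) Sex + log(1.05) Age / 10 +
#' G_std beta + (Sex * G_std) gamma + epsilon`, where `pi0_k` is a
#' population-specific baseline prevalence.
#'
#' @param Gstd standardized candidate genotypes.
#' @param population integer population labels.
#' @param pi0 baseline prevalence per population.
#' @param sex binary exposure vector.
#' @param age age covariate (years).
#' @param beta,gamma effect vectors.
#' @param epsilon polygenic random effect draw.
#' @return List with `y` and the linear predictor `eta`.
#' @export
simulatePhenotypes <- function(Gstd, population, pi0, sex, age, beta, gamma,
                               epsilon) {
  n <- nrow(Gstd)
  if (any(is.na(population)) || any(population < 1) ||
      any(population > length(pi0)))
    stop("missing or out-of-range population label")
  eta <- qlogis(pi0[population]) - log(1.3) * sex + log(1.05) * age / 10 +
    as.numeric(Gstd %*% beta) + as.numeric((sex * Gstd) %*% gamma) +
    epsilon
  list(y = rbinom(n, 1, plogis(eta)), eta = eta)
}

#' Generate a complete structured gene-environment dataset
#'
#' End-to-end synthetic-data generator: structured genotypes for the
#' candidate panel and a disjoint kinship panel (same samples and
#' populations), the kinship pair (GRM from standardized kinship-panel
#' genotypes, stabilized, masked by the binary exposure), sparse causal
#' effects, the two-component polygenic draw, covariates
#' (`age ~ N(50, 10)`, `sex ~ Bernoulli(0.5)` as the exposure), baseline
#' prevalences `pi0_k ~ U(0.1, 0.9)` and binary phenotypes. Fully
#' reproducible from `config$seed`.
#'
#' @param config a [simulationConfig()] list.
#' @param popExposure optional vector of per-population exposure
#'   probabilities inducing gene-environment dependence (default: common
#'   0.5).
#' @return A [SimulatedData-class].
#' @export
simulateGxEData <- function(config = simulationConfig(),
                            popExposure = NULL) {
  withSeed(config$seed, {
    cand <- simulateStructuredGenotypes(config$n, config$p,
                                        nPops = config$nPops,
                                        Fst = config$Fst,
                                        popWeights = config$popWeights,
                                        idPrefix = "cand")
    kin <- simulateStructuredGenotypes(config$n, config$kinshipSnps,
                                       nPops = config$nPops,
                                       Fst = config$Fst,
                                       population = cand$population,
                                       idPrefix = "kin")
    K <- stabilizePSD(computeGRM(standardizeGenotypes(kin$panel)))
    sexProb <- if (is.null(popExposure)) rep(0.5, config$nPops)
               else rep_len(popExposure, config$nPops)
    sex <- rbinom(config$n, 1, sexProb[cand$population])
    kp <- buildGxEKinship(K, sex, kind = "binary")
    eff <- drawEffects(config)
    epsilon <- simulateRandomEffect(kinshipMatrix(kp), gxeKinshipMatrix(kp),
                                    config$h2G, config$h2D, config$sigma2)
    age <- rnorm(config$n, 50, 10)
    pi0 <- runif(config$nPops, 0.1, 0.9)
    Gstd <- standardizeGenotypes(cand$panel)
    ph <- simulatePhenotypes(Gstd, cand$population, pi0, sex, age,
                             eff$beta, eff$gamma, epsilon)
    new("SimulatedData",
        panel = cand$panel, population = cand$population,
        age = age, sex = as.numeric(sex),
        beta = eff$beta, gamma = eff$gamma,
        causalMain = as.integer(eff$S), causalGEI = as.integer(eff$Sprime),
        epsilon = epsilon, y = as.numeric(ph$y), kinship = kp,
        config = config)
  })
}
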