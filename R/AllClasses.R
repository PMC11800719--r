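#' @import methods
#' @importFrom Matrix Matrix
NULL

#' Genotype panel
#'
#' Container for a matrix of minor-allele counts together with per-SNP
#' minor allele frequencies and identifiers. Genotypes take values 0, 1, 2
#' (missing allowed as `NA`); MAFs lie strictly inside (0, 1) so that every
#' retained SNP is polymorphic and can be standardized.
#'
#' @slot genotypes n x p numeric matrix of minor-allele counts.
#' @slot maf length-p numeric vector of minor allele frequencies.
#' @slot sampleIds length-n character vector.
#' @slot snpIds length-p character vector.
#'
#' @seealso [GenotypePanel()], [standardizeGenotypes()], [computeGRM()]
#' @export
setClass("GenotypePanel",
  representation(
    genotypes = "matrix",
    maf = "numeric",
    sampleIds = "character",
    snpIds = "character"
  )
)

setValidity("GenotypePanel", function(object) {
  g <- object@genotypes
  msg <- character()
  bad <- g[!is.na(g)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    msg <- c(msg, "genotype entries must be in {0, 1, 2} or NA")
  if (ncol(g) != length(object@maf))
    msg <- c(msg, "length(maf) must equal ncol(genotypes)")
  if (length(object@maf) && (any(object@maf <= 0) || any(object@maf >= 1)))
    msg <- c(msg, "maf must lie strictly inside (0, 1)")
  if (nrow(g) != length(object@sampleIds))
    msg <- c(msg, "length(sampleIds) must equal nrow(genotypes)")
  if (ncol(g) != length(object@snpIds))
    msg <- c(msg, "length(snpIds) must equal ncol(genotypes)")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypePanel
#'
#' @param genotypes n x p matrix of minor-allele counts in {0, 1, 2}
#'   (`NA` allowed).
#' @param maf optional length-p MAF vector; computed from the sample
#'   (mean(g)/2 over non-missing entries) when `NULL`.
#' @param sampleIds,snpIds optional identifier vectors; defaults are
#'   generated from dimnames or positional labels.
#' @param dropMonomorphic drop SNPs whose sample MAF is 0 or 1 instead of
#'   failing validity.
#'
#' @return A [GenotypePanel-class] object.
#' @examples
#' g <- matrix(c(0, 1, 2, 1, 0, 1), nrow = 3)
#' GenotypePanel(g)
#' @export
GenotypePanel <- function(genotypes, maf = NULL, sampleIds = NULL,
                          snpIds = NULL, dropMonomorphic = FALSE) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  if (is.null(sampleIds))
    sampleIds <- rownames(genotypes) %||% paste0("sample", seq_len(nrow(genotypes)))
  if (is.null(snpIds))
    snpIds <- colnames(genotypes) %||% paste0("snp", seq_len(ncol(genotypes)))
  if (is.null(maf)) {
    maf <- colMeans(genotypes, na.rm = TRUE) / 2
    mono <- !is.finite(maf) | maf <= 0 | maf >= 1
    if (any(mono)) {
      if (!dropMonomorphic)
        stop("monomorphic SNP(s): ", paste(snpIds[mono], collapse = ", "),
             "; remove them or use dropMonomorphic = TRUE")
      genotypes <- genotypes[, !mono, drop = FALSE]
      maf <- maf[!mono]
      snpIds <- snpIds[!mono]
    }
  }
  new("GenotypePanel", genotypes = genotypes, maf = as.numeric(maf),
      sampleIds = as.character(sampleIds), snpIds = as.character(snpIds))
}

#' Kinship pair (K, K_D)
#'
#' Holds the genetic similarity matrix K and the gene-by-environment
#' kinship K_D derived from an exposure vector. For a binary exposure,
#' `K_D[i, j] = K[i, j]` when the two subjects share the exposure level and
#' 0 otherwise; for a continuous exposure `K_D[i, j] = K[i, j] (1 - d_ij)`
#' with a similarity-distance `d` mapping into [0, 1]. Entrywise,
#' `|K_D| <= |K|` always holds.
#'
#' @slot K n x n symmetric genetic similarity matrix.
#' @slot KD n x n symmetric exposure-masked kinship.
#' @slot exposure length-n exposure vector.
#' @slot exposureKind `"binary"` or `"continuous"`.
#' @export
setClass("KinshipPair",
  representation(
    K = "matrix",
    KD = "matrix",
    exposure = "numeric",
    exposureKind = "character"
  )
)

setValidity("KinshipPair", function(object) {
  msg <- character()
  if (!isSymmetric(object@K, tol = 1e-8))
    msg <- c(msg, "K must be symmetric")
  if (!isSymmetric(object@KD, tol = 1e-8))
    msg <- c(msg, "KD must be symmetric")
  if (!all(dim(object@K) == dim(object@KD)))
    msg <- c(msg, "K and KD must have the same dimension")
  if (length(object@exposure) != nrow(object@K))
    msg <- c(msg, "exposure length must equal nrow(K)")
  if (!object@exposureKind %in% c("binary", "continuous"))
    msg <- c(msg, "exposureKind must be 'binary' or 'continuous'")
  if (any(abs(object@KD) > abs(object@K) + 1e-8))
    msg <- c(msg, "|KD| must not exceed |K| entrywise")
  if (length(msg)) msg else TRUE
})

#' Spectral basis of the random-effect covariance
#'
#' Eigendecomposition U diag(evalues) U' of tau_g K + tau_d K_D, computed
#' once per variance-component estimate and reused along the whole
#' regularization path. Eigenvalues are sorted in decreasing order and must
#' all be positive (stabilize K first if necessary).
#'
#' @slot U n x n orthonormal eigenvector matrix.
#' @slot evalues length-n positive eigenvalues, decreasing.
#' @slot tau named numeric `(g, d)` used to form the decomposed matrix.
#' @export
setClass("SpectralBasis",
  representation(U = "matrix", evalues = "numeric", tau = "numeric")
)

setValidity("SpectralBasis", function(object) {
  msg <- character()
  if (nrow(object@U) != ncol(object@U))
    msg <- c(msg, "U must be square")
  if (length(object@evalues) != nrow(object@U))
    msg <- c(msg, "evalues length must equal nrow(U)")
  if (length(object@evalues) && any(object@evalues <= 0))
    msg <- c(msg, "all eigenvalues must be positive (stabilize K first)")
  if (is.unsorted(rev(object@evalues)))
    msg <- c(msg, "eigenvalues must be sorted in decreasing order")
  if (length(msg)) msg else TRUE
})

#' Model family for quasi-likelihood working models
#'
#' Minimal exponential-family descriptor with canonical link: binomial
#' (logit link, variance mu(1-mu), dispersion fixed at 1) or gaussian
#' (identity link, variance 1, dispersion estimated). Prior weights a_i
#' enter the working weights as w_i = a_i / (phi * nu(mu) g'(mu)^2).
#'
#' @slot name `"binomial"` or `"gaussian"`.
#' @slot phi dispersion parameter (`NA` until estimated for gaussian).
#' @export
setClass("FamilySpec", representation(name = "character", phi = "numeric"))

setValidity("FamilySpec", function(object) {
  if (!object@name %in% c("binomial", "gaussian"))
    return("family name must be 'binomial' or 'gaussian'")
  if (object@name == "binomial" && !isTRUE(all.equal(object@phi, 1)))
    return("binomial dispersion is fixed at 1")
  TRUE
})

#' Null-model fit (variance components under beta = gamma = 0)
#'
#' Result of the two-step strategy: covariate and exposure effects, the
#' variance components (tau_g, tau_d), the dispersion and the predicted
#' random-effect vector are estimated once, assuming no genetic fixed
#' effects, by PQL working-model iterations with AI-REML updates.
#'
#' @slot theta covariate fixed effects (first element is the intercept).
#' @slot alpha exposure fixed effect.
#' @slot tau named numeric `(g, d)`, each >= 0 (`d` absent for a single
#'   random effect).
#' @slot phi dispersion (1 for binomial).
#' @slot b length-n predicted random effects.
#' @slot eta,mu working linear predictor and mean at convergence.
#' @slot scores REML score components per variance parameter, divided by n.
#' @slot converged logical convergence flag.
#' @slot nIter outer iterations used.
#' @slot family the [FamilySpec-class] used.
#' @export
setClass("NullFit",
  representation(
    theta = "numeric",
    alpha = "numeric",
    tau = "numeric",
    phi = "numeric",
    b = "numeric",
    eta = "numeric",
    mu = "numeric",
    scores = "numeric",
    converged = "logical",
    nIter = "integer",
    family = "FamilySpec"
  )
)

#' Regularization path fit
#'
#' Solution path of the penalized working objective over the (lambda, rho)
#' grid. Coefficients are stored sparsely (one column per path point);
#' strong hierarchy (`gamma[j] != 0` implies `beta[j] != 0`) holds at every
#' point by construction of the proximal operator.
#'
#' @slot lambda,rho per-point penalty values (length = number of points).
#' @slot lambdaMax named-by-rho vector of per-rho lambda maxima.
#' @slot beta,gamma p x npoints sparse coefficient matrices.
#' @slot theta (m+1) x npoints unpenalized covariate coefficients
#'   (intercept first).
#' @slot alpha per-point exposure effect.
#' @slot b n x npoints random-effect predictions.
#' @slot objective per-point penalized objective value.
#' @slot sizeMain,sizeGEI per-point model sizes (non-zero beta / gamma).
#' @slot iterations per-point outer iteration counts.
#' @slot converged per-point convergence flags.
#' @slot snpIds predictor identifiers.
#' @slot family the [FamilySpec-class] used.
#' @export
setClass("PathFit",
  representation(
    lambda = "numeric",
    rho = "numeric",
    lambdaMax = "numeric",
    beta = "Matrix",
    gamma = "Matrix",
    theta = "matrix",
    alpha = "numeric",
    b = "matrix",
    objective = "numeric",
    sizeMain = "integer",
    sizeGEI = "integer",
    iterations = "integer",
    converged = "logical",
    snpIds = "character",
    family = "FamilySpec"
  )
)

setValidity("PathFit", function(object) {
  np <- length(object@lambda)
  msg <- character()
  if (length(object@rho) != np) msg <- c(msg, "rho/lambda length mismatch")
  if (ncol(object@beta) != np || ncol(object@gamma) != np)
    msg <- c(msg, "coefficient matrices must have one column per point")
  hier <- violatesHierarchy(object@beta, object@gamma)
  if (any(hier))
    msg <- c(msg, "hierarchy violated: gamma non-zero without its beta")
  if (length(msg)) msg else TRUE
})

#' Cross-validation result over the penalty grid
#'
#' @slot metric name of the validation metric (`"deviance"` or `"auc"`).
#' @slot metricMean,metricSE nLambda x nRho matrices of fold-averaged
#'   metric and its standard error.
#' @slot lambdaGrid nLambda x nRho matrix of lambda values (per-rho grids).
#' @slot rhoGrid length-nRho vector.
#' @slot lambdaBest,rhoBest selected penalty pair.
#' @slot foldIds integer fold assignment per sample.
#' @slot fit full-data [PathFit-class] on the same grid.
#' @slot bestIndex index of the selected point within `fit`.
#' @export
setClass("CVFit",
  representation(
    metric = "character",
    metricMean = "matrix",
    metricSE = "matrix",
    lambdaGrid = "matrix",
    rhoGrid = "numeric",
    lambdaBest = "numeric",
    rhoBest = "numeric",
    foldIds = "integer",
    fit = "PathFit",
    bestIndex = "integer"
  )
)

#' Simulated structured gene-environment dataset
#'
#' Output of the synthetic-data generator: a candidate genotype panel with
#' population labels, covariates, a binary exposure, sparse true effect
#' vectors, a two-component polygenic random effect, binary phenotypes and
#' a kinship pair computed from a disjoint SNP set.
#'
#' @slot panel candidate [GenotypePanel-class] (p SNPs).
#' @slot population integer population label per sample.
#' @slot age,sex covariate vectors; `sex` is the binary exposure.
#' @slot beta,gamma length-p true effect vectors.
#' @slot causalMain,causalGEI index sets S and S' of non-zero effects.
#' @slot epsilon length-n polygenic + polygenic-by-environment draw.
#' @slot y binary phenotypes.
#' @slot kinship [KinshipPair-class] built from SNPs disjoint from the
#'   candidates.
#' @slot config the generating parameter list.
#' @export
setClass("SimulatedData",
  representation(
    panel = "GenotypePanel",
    population = "integer",
    age = "numeric",
    sex = "numeric",
    beta = "numeric",
    gamma = "numeric",
    causalMain = "integer",
    causalGEI = "integer",
    epsilon = "numeric",
    y = "numeric",
    kinship = "KinshipPair",
    config = "list"
  )
)

setValidity("SimulatedData", function(object) {
  msg <- character()
  if (!all(object@y %in% c(0, 1))) msg <- c(msg, "phenotypes must be binary")
  if (!all(which(object@gamma != 0) %in% object@causalGEI))
    msg <- c(msg, "non-zero gamma outside the declared GEI causal set")
  if (isTRUE(object@config$hierarchy) &&
      !all(object@causalGEI %in% object@causalMain))
    msg <- c(msg, "hierarchy flag set but S' is not a subset of S")
  if (length(msg)) msg else TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a
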