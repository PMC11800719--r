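#' @include AllClasses.R
NULL

#' Accessors
#'
#' Accessor generics for the core classes: genotype matrices, MAFs,
#' identifiers, kinship matrices, spectral components, variance components
#' and random effects.
#'
#' @param x an object of the documented classes.
#' @param ... unused.
#' @return The corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genotypes", function(x, ...) standardGeneric("genotypes"))
#' @rdname accessors
#' @export
setGeneric("maf", function(x, ...) standardGeneric("maf"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("snpIds", function(x, ...) standardGeneric("snpIds"))
#' @rdname accessors
#' @export
setGeneric("kinshipMatrix", function(x, ...) standardGeneric("kinshipMatrix"))
#' @rdname accessors
#' @export
setGeneric("gxeKinshipMatrix", function(x, ...) standardGeneric("gxeKinshipMatrix"))
#' @rdname accessors
#' @export
setGeneric("exposure", function(x, ...) standardGeneric("exposure"))
#' @rdname accessors
#' @export
setGeneric("eigenVectors", function(x, ...) standardGeneric("eigenVectors"))
#' @rdname accessors
#' @export
setGeneric("eigenValues", function(x, ...) standardGeneric("eigenValues"))
#' @rdname accessors
#' @export
setGeneric("varianceComponents", function(x, ...) standardGeneric("varianceComponents"))
#' @rdname accessors
#' @export
setGeneric("randomEffects", function(x, ...) standardGeneric("randomEffects"))
#' @rdname accessors
#' @export
setGeneric("modelSizes", function(x, ...) standardGeneric("modelSizes"))

#' @rdname accessors
#' @export
setMethod("genotypes", "GenotypePanel", function(x, ...) x@genotypes)
#' @rdname accessors
#' @export
setMethod("maf", "GenotypePanel", function(x, ...) x@maf)
#' @rdname accessors
#' @export
setMethod("sampleIds", "GenotypePanel", function(x, ...) x@sampleIds)
#' @rdname accessors
#' @export
setMethod("snpIds", "GenotypePanel", function(x, ...) x@snpIds)
#' @rdname accessors
#' @export
setMethod("kinshipMatrix", "KinshipPair", function(x, ...) x@K)
#' @rdname accessors
#' @export
setMethod("gxeKinshipMatrix", "KinshipPair", function(x, ...) x@KD)
#' @rdname accessors
#' @export
setMethod("exposure", "KinshipPair", function(x, ...) x@exposure)
#' @rdname accessors
#' @export
setMethod("eigenVectors", "SpectralBasis", function(x, ...) x@U)
#' @rdname accessors
#' @export
setMethod("eigenValues", "SpectralBasis", function(x, ...) x@evalues)
#' @rdname accessors
#' @export
setMethod("varianceComponents", "NullFit", function(x, ...)
  c(x@tau, phi = unname(x@phi)))
#' @rdname accessors
#' @export
setMethod("randomEffects", "NullFit", function(x, ...) x@b)

#' @rdname accessors
#' @export
setMethod("modelSizes", "PathFit", function(x, ...)
  data.frame(rho = x@rho, lambda = x@lambda,
             sizeMain = x@sizeMain, sizeGEI = x@sizeGEI))

#' Extract coefficients from a path fit
#'
#' @param object a [PathFit-class].
#' @param point integer index of the path point (default: last).
#' @param ... unused.
#' @return A list with `theta`, `alpha`, `beta`, `gamma`, `lambda`, `rho`.
#' @export
setMethod("coef", "PathFit", function(object, point = length(object@lambda), ...) {
  stopifnot(point >= 1, point <= length(object@lambda))
  list(theta = object@theta[, point],
       alpha = object@alpha[point],
       beta = as.numeric(object@beta[, point]),
       gamma = as.numeric(object@gamma[, point]),
       lambda = object@lambda[point],
       rho = object@rho[point])
})

#' @describeIn CVFit-class coefficients at the cross-validated optimum.
#' @param object a [CVFit-class].
#' @param ... unused.
#' @export
setMethod("coef", "CVFit", function(object, ...)
  coef(object@fit, point = object@bestIndex))

setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel:", nrow(object@genotypes), "samples x",
      ncol(object@genotypes), "SNPs\n")
  cat("  MAF range:", sprintf("[%.3f, %.3f]",
      min(object@maf), max(object@maf)), "\n")
  nm <- sum(is.na(object@genotypes))
  if (nm) cat("  missing genotypes:", nm, "\n")
})

setMethod("show", "KinshipPair", function(object) {
  cat("KinshipPair:", nrow(object@K), "x", ncol(object@K),
      sprintf("(%s exposure)\n", object@exposureKind))
  cat("  mean diag(K):", sprintf("%.4f", mean(diag(object@K))),
      " zero fraction of KD off-diagonal:",
      sprintf("%.3f", mean(object@KD[upper.tri(object@KD)] == 0)), "\n")
})

setMethod("show", "SpectralBasis", function(object) {
  cat("SpectralBasis: n =", nrow(object@U),
      sprintf(" tau = (g: %.4g, d: %.4g)\n",
              object@tau[["g"]],
              if ("d" %in% names(object@tau)) object@tau[["d"]] else 0))
  cat("  eigenvalues in",
      sprintf("[%.4g, %.4g]\n", min(object@evalues), max(object@evalues)))
})

setMethod("show", "NullFit", function(object) {
  cat("NullFit (", object@family@name, " family)\n", sep = "")
  cat("  tau:", paste(sprintf("%s = %.4g", names(object@tau), object@tau),
                      collapse = ", "),
      " phi:", sprintf("%.4g", object@phi), "\n")
  cat("  converged:", object@converged, "in", object@nIter, "iterations\n")
})

setMethod("show", "PathFit", function(object) {
  cat("PathFit:", length(object@lambda), "path points,",
      length(unique(object@rho)), "rho values,",
      nrow(object@beta), "SNP groups\n")
  cat("  model size range: main",
      sprintf("[%d, %d]", min(object@sizeMain), max(object@sizeMain)),
      " GEI", sprintf("[%d, %d]", min(object@sizeGEI), max(object@sizeGEI)),
      "\n")
  if (!all(object@converged))
    cat("  warning:", sum(!object@converged), "non-converged points\n")
})

setMethod("show", "CVFit", function(object) {
  cat("CVFit (", object@metric, ", ", max(object@foldIds), " folds)\n",
      sep = "")
  cat("  selected: lambda =", sprintf("%.4g", object@lambdaBest),
      " rho =", sprintf("%.2f", object@rhoBest), "\n")
  cs <- coef(object)
  cat("  final model size: main", sum(cs$beta != 0),
      " GEI", sum(cs$gamma != 0), "\n")
})

setMethod("show", "SimulatedData", function(object) {
  cat("SimulatedData:", length(object@y), "samples,",
      ncol(object@panel@genotypes), "candidate SNPs\n")
  cat("  causal: |S| =", length(object@causalMain),
      " |S'| =", length(object@causalGEI),
      " hierarchy:", isTRUE(object@config$hierarchy), "\n")
  cat("  case fraction:", sprintf("%.3f", mean(object@y)), "\n")
})
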