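#' Write fitted path and cross-validation results
#'
#' Emits plain-text artifacts for a fitted path (and optionally its
#' cross-validation): `coefficients.tsv` (long format: rho, lambda,
#' coefficient name, value, non-zero entries only, unpenalized effects
#' always included), `path_summary.tsv` (per-point objective, model sizes,
#' iterations, convergence), `cv_surface.tsv` (fold-averaged metric per
#' grid cell) and `final_model.tsv` (selected coefficients with odds-ratio
#' columns `exp(beta)`, `exp(gamma)`, `exp(beta + gamma)`).
#'
#' @param fit a [PathFit-class].
#' @param outDir output directory (created if missing).
#' @param cv optional [CVFit-class] for the surface and final model.
#' @return Character vector of written files, invisibly.
#' @export
writePathResults <- function(fit, outDir, cv = NULL) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  written <- character()

  longRows <- list()
  for (ptIdx in seq_along(fit@lambda)) {
    cs <- coef(fit, ptIdx)
    nm <- c(paste0("theta.", seq_along(cs$theta) - 1L),
            if (!is.na(cs$alpha)) "alpha")
    val <- c(cs$theta, if (!is.na(cs$alpha)) cs$alpha)
    act <- which(cs$beta != 0)
    nm <- c(nm, paste0("beta.", fit@snpIds[act]))
    val <- c(val, cs$beta[act])
    actG <- which(cs$gamma != 0)
    nm <- c(nm, paste0("gamma.", fit@snpIds[actG]))
    val <- c(val, cs$gamma[actG])
    longRows[[ptIdx]] <- data.frame(rho = cs$rho, lambda = cs$lambda,
                                    coefficient = nm, value = val)
  }
  coefFile <- file.path(outDir, "coefficients.tsv")
  utils::write.table(do.call(rbind, longRows), coefFile, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  written <- c(written, coefFile)

  summaryFile <- file.path(outDir, "path_summary.tsv")
  utils::write.table(
    data.frame(rho = fit@rho, lambda = fit@lambda,
               objective = fit@objective, sizeMain = fit@sizeMain,
               sizeGEI = fit@sizeGEI, iterations = fit@iterations,
               converged = fit@converged),
    summaryFile, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, summaryFile)

  if (!is.null(cv)) {
    surf <- expand.grid(lambdaIndex = seq_len(nrow(cv@metricMean)),
                        rho = cv@rhoGrid)
    surf$lambda <- as.vector(cv@lambdaGrid)
    surf$metricMean <- as.vector(cv@metricMean)
    surf$metricSE <- as.vector(cv@metricSE)
    surfFile <- file.path(outDir, "cv_surface.tsv")
    utils::write.table(surf, surfFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    finalFile <- file.path(outDir, "final_model.tsv")
    utils::write.table(oddsRatioTable(coef(cv), fit@snpIds), finalFile,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, surfFile, finalFile)
  }
  invisible(written)
}

#' Odds-ratio table of a selected model
#'
#' One row per selected SNP with the estimated coefficients and odds
#' ratios `exp(beta)`, `exp(gamma)` and `exp(beta + gamma)` (the exposed
#' group's per-allele odds ratio). Empty support yields a zero-row table
#' with a valid header.
#'
#' @param coefs coefficient list (see `coef` on [PathFit-class]).
#' @param snpIds predictor identifiers.
#' @return `data.frame` with columns snp, beta, gamma, ORbeta, ORgamma,
#'   ORbetaGamma.
#' @export
oddsRatioTable <- function(coefs, snpIds = NULL) {
  act <- which(coefs$beta != 0 | coefs$gamma != 0)
  if (is.null(snpIds)) snpIds <- paste0("snp", seq_along(coefs$beta))
  data.frame(snp = snpIds[act],
             beta = coefs$beta[act],
             gamma = coefs$gamma[act],
             ORbeta = exp(coefs$beta[act]),
             ORgamma = exp(coefs$gamma[act]),
             ORbetaGamma = exp(coefs$beta[act] + coefs$gamma[act]))
}

#' Serialize / restore a null fit
#'
#' Scalars (fixed effects, variance components, dispersion, convergence
#' information) go to JSON; the random-effect vector to a one-column text
#' file next to it.
#'
#' @param fit a [NullFit-class].
#' @param path JSON output path (`<path>.b.txt` holds the random effects).
#' @return `path`, invisibly (writer); a list (reader).
#' @export
writeNullFit <- function(fit, path) {
  jsonlite::write_json(
    list(family = fit@family@name, theta = fit@theta, alpha = fit@alpha,
         tau = as.list(fit@tau), phi = fit@phi,
         converged = fit@converged, nIter = fit@nIter,
         scores = fit@scores),
    path, auto_unbox = TRUE, digits = NA)
  utils::write.table(data.frame(b = fit@b), paste0(path, ".b.txt"),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeNullFit
#' @export
readNullFit <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  js$b <- utils::read.table(paste0(path, ".b.txt"), header = TRUE)$b
  js
}
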