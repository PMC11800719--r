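#' Model families
#'
#' Constructors for the two supported exponential families with canonical
#' links. The binomial family uses the logit link with variance function
#' `nu(mu) = mu (1 - mu)` and dispersion fixed at 1 (standard PQL for
#' binary traits); the gaussian family uses the identity link with
#' `nu(mu) = 1` and its dispersion estimated by REML in the null model.
#'
#' @param phi dispersion parameter for the gaussian family (`NA` until
#'   estimated).
#' @return A [FamilySpec-class] object.
#' @examples
#' binomialFamily()
#' gaussianFamily()
#' @export
binomialFamily <- function() new("FamilySpec", name = "binomial", phi = 1)

#' @rdname binomialFamily
#' @export
gaussianFamily <- function(phi = NA_real_)
  new("FamilySpec", name = "gaussian", phi = phi)

## inverse link
famLinkinv <- function(family, eta) {
  switch(family@name,
    binomial = plogis(eta),
    gaussian = eta)
}

## derivative of the link g'(mu); canonical, so g'(mu) = 1 / nu(mu)
famLinkDeriv <- function(family, mu) {
  switch(family@name,
    binomial = 1 / (mu * (1 - mu)),
    gaussian = rep_len(1, length(mu)))
}

famVariance <- function(family, mu) {
  switch(family@name,
    binomial = mu * (1 - mu),
    gaussian = rep_len(1, length(mu)))
}

## negative quasi-likelihood contributions -ql_i (phi = 1 scale for
## binomial; gaussian divides by phi)
famNegQL <- function(family, y, eta, phi = family@phi) {
  switch(family@name,
    ## -[y eta - log(1 + e^eta)], numerically stable log1p
    binomial = log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta,
    gaussian = (y - eta)^2 / (2 * phi))
}

famDevianceResiduals <- function(family, y, mu) {
  switch(family@name,
    binomial = -2 * (y * log(pmax(mu, 1e-12)) +
                     (1 - y) * log(pmax(1 - mu, 1e-12))),
    gaussian = (y - mu)^2)
}

#' Working weights of the quasi-likelihood model
#'
#' Diagonal of the weight matrix `W = phi^-1 diag{a_i nu(mu_i) g'(mu_i)^2}^-1`
#' of the PQL working model. For the canonical binomial family this reduces
#' to `w_i = a_i mu_i (1 - mu_i) / phi`; for the gaussian identity family to
#' `w_i = a_i / phi`.
#'
#' @param mu mean vector, strictly inside the mean domain (binomial:
#'   (0, 1)).
#' @param family a [FamilySpec-class].
#' @param priorWeights known prior weights `a_i` (default 1).
#' @param phi dispersion; defaults to the family's value.
#' @return Numeric vector of positive weights.
#' @examples
#' workingWeights(0.5, binomialFamily())  # 0.25
#' @export
workingWeights <- function(mu, family, priorWeights = 1, phi = family@phi) {
  if (family@name == "binomial" && (any(mu <= 0) || any(mu >= 1)))
    stop("mean on the boundary of (0, 1): degenerate fit (separation?)")
  if (is.na(phi)) phi <- 1
  a <- rep_len(priorWeights, length(mu))
  w <- a / (phi * famVariance(family, mu) * famLinkDeriv(family, mu)^2)
  if (any(!is.finite(w)) || any(w <= 0))
    stop("non-positive or non-finite working weight")
  w
}

## working response z = eta + (y - mu) g'(mu)
workingResponse <- function(family, y, eta, mu)
  eta + (y - mu) * famLinkDeriv(family, mu)
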