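---
title: "Hierarchical gene-environment interaction selection in penalized logistic mixed models"
author: "hierGxE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical gene-environment interaction selection in penalized logistic mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Genome-wide searches for gene-environment interactions (GEI) on a binary
trait face two compounding difficulties. First, the design is
high-dimensional twice over: each of p candidate SNPs contributes a main
effect and an interaction with the exposure, so 2p + m + 1 coefficients
compete for n observations. Second, population structure, cryptic
relatedness and *shared exposure* within relatives or subpopulations
create spurious associations for both main and interaction terms; the
classical principal-component adjustment corrects the former reasonably
well but does nothing specific for the latter.

hierGxE addresses both with a logistic mixed model carrying **two**
kinship-structured random effects, estimated by penalized
quasi-likelihood (PQL), combined with a sparse group lasso penalty that
performs hierarchical selection of main and GEI effects.

## Model

For subject i with covariates Z_i, binary (or continuous) exposure D_i
and minor-allele counts G_i in {0, 1, 2}:

    g(mu_i) = Z_i theta + D_i alpha + G_i beta + (D_i G_i) gamma + b_i
    b ~ N(0, tau_g K + tau_d K_D)

with canonical link g. K is the genetic similarity matrix computed from
standardized genotypes (`K = G_std G_std' / p`, the PLINK `--make-rel`
convention) on a SNP set disjoint from the candidates. K_D encodes joint
genetic *and* environmental similarity: for a binary exposure
`K_D[i, j] = K[i, j]` when D_i = D_j and 0 otherwise; for a continuous
exposure, K is damped by a [0, 1]-valued exposure distance (default:
range-normalized absolute difference; the construction only requires the
distance to map into [0, 1]). K_D absorbs the polygenic background of
*interaction* effects exactly as K absorbs the polygenic background of
main effects, and is what suppresses spurious GEI selection under shared
exposure.

## Estimation: the two-step strategy

Joint optimization of variance components with 2p + m + 1 penalized fixed
effects would require O(n^3) matrix work inside every penalty-grid
iteration. Instead:

**Step 1 (null model).** With beta = gamma = 0, the PQL working model
`z = eta + (y - mu) g'(mu)`, `V = W^-1 + tau_g K + tau_d K_D` is iterated
with one average-information REML update of (tau_g, tau_d) per weight
refresh (`fitNull()`). Implementation notes:

* score_k = (z'P K_k P z - tr(P K_k)) / 2 and
  AI_kl = z'P K_k P K_l P z / 2 with the usual REML projection P; traces
  use `tr(AB) = sum(A * B)` for symmetric A, B, so one Cholesky inversion
  per iteration is the only O(n^3) step.
* Components pinned at the zero boundary with negative score are removed
  from the AI system before solving; this prevents a boundary component
  from tilting the update of interior components (the deadlock otherwise
  occurs in practice). Step-halving against the REML objective guards
  every update, with a scaled-gradient fallback.
* Dispersion phi is fixed at 1 for the binomial family (standard PQL for
  binary traits) and estimated as a variance component (kernel I) for the
  gaussian test family. With K = I the gaussian pair (tau, phi) is only
  jointly identified; the AI solve carries a small ridge and the
  identifiable sum matches closed-form REML.
* Convergence: relative parameter change < 1e-4 and REML scores per
  observation < 1e-3 (boundary components exempt when their score is
  negative), at most 50 outer iterations.
* Covariates enter on their original scale; they are not standardized.

PQL is known to attenuate variance components for binary traits; the
attenuation shrinks as the effective number of observations sharing a
random-effect level grows. On block kinship with 50-member blocks the
bias for (tau_g, tau_d) = (1.8, 0.9) is well under 10%; with 20-member
blocks it approaches 25%. Downstream selection uses tau only through the
ridge on the random effects, so moderate attenuation costs little.

**Step 2 (penalized path).** With (tau_g, tau_d) fixed, the combined
covariance is eigendecomposed once, `tau_g K + tau_d K_D = U Lambda U'`
(`spectralDecompose()`; K is ridge-stabilized by `K + 1e-4 I` first when
its smallest eigenvalue is at or below 1e-8). Rotated random effects
`delta = U'b` turn the random-effect term into a generalized ridge with
diagonal matrix Lambda^-1, and the objective at penalty level
(lambda, rho) is

    Q = -sum_i ql_i(Theta; delta) + delta' Lambda^-1 delta / 2
        + (1 - rho) lambda sum_j ||(beta_j, gamma_j)||_2
        + rho lambda sum_j |gamma_j|

The sparse group lasso penalty couples each SNP's main and GEI
coefficient into one group. Its proximal operator is closed-form
(soft-threshold gamma at `t rho lambda`, then group-shrink the pair at
`t (1 - rho) lambda`), and it enforces **strong hierarchy**: gamma_j can
be non-zero only when the group survives, in which case beta_j survives
with it, while the extra L1 pressure on gamma lets main effects be
selected alone. rho = 0 is the pure group lasso (pairs enter together);
the exposure effect alpha and the covariates are never penalized.

## The path algorithm

`fitPath()` is a proximal Newton method with block coordinate descent:

1. At the current iterate, form the working response and weights and
   freeze the weights (they vary slowly with the conditional mean).
2. Update delta by the generalized ridge weighted least squares solve
   `(diag(w) + Sigma^-1) b = w r` (solved unrotated; algebraically
   identical to the rotated `(U'WU + Lambda^-1) delta = U'W r`).
3. Update Theta by block coordinate descent on the frozen quadratic:
   the unpenalized block (theta, alpha) by one exact weighted
   least-squares solve per cycle (a factorization is reused within the
   call; coordinate-wise updates zig-zag badly when covariates are
   correlated with the intercept), and each group (beta_j, gamma_j) by
   the *exact* minimizer of its 2x2 local quadratic, found by O(1)
   majorized prox iterations with step 1/lambda_max(H_j) before the
   residual is touched. The interaction column D * G_j is treated as a
   row-scaling of G_j and never materialized.
4. Active-set screening: the descent runs on the current support; one
   BLAS gradient pass then checks the sparse-group KKT condition for all
   left-out groups, admits violators, and repeats until none remain.
5. Monotonicity guard: if Q increases (stale weights can overshoot), the
   step is halved toward the previous iterate up to 10 times; a point
   that still fails is recorded as non-converged and the path continues.

Tolerances: inner BCD stops at 1e-7 maximum absolute coefficient change
(cap 100 cycles per proximal step); the outer loop stops at 1e-6 relative
objective change (cap 50). Ties at the group threshold go to zero (the
closed-form prox maps the boundary to 0).

`lambda_max(rho)` is the smallest lambda whose subgradient condition
`||(grad_beta_j, soft(grad_gamma_j, rho lambda))|| <= (1 - rho) lambda`
holds for every group at the null-covariate fit — closed form
`max_j ||(grad_beta_j, grad_gamma_j)||` at rho = 0, per-group bisection
otherwise. Each rho sweep starts at its own lambda_max from the
null-covariate fit and warm-starts down a log10-spaced grid of 50 values
to 0.01 lambda_max (both defaults); the default 10 rho values span
[0, 0.9], giving 500 path models.

## Tuning and prediction

`crossValidate()` evaluates the whole (lambda, rho) grid by stratified
k-fold cross-validation (default 10 folds, binomial deviance; AUC by
flag). Following the two-step philosophy, variance components and the
per-rho lambda grids come from the full data; each fold refits the path
on its training block with the covariance restricted and re-decomposed.
Held-out subjects are scored with fixed effects only by default; a
conditional-Gaussian transfer of the random effect through cross-kinship
blocks (`b_new = Sigma[new, train] Sigma[train, train]^-1 b_train`) is
available both here and in `predictProbabilities()`, because no single
convention exists for carrying polygenic effects to unseen samples. Ties
on the metric surface resolve to the larger lambda, then the smaller rho;
a one-standard-error rule is off by default.

## The synthetic-data generator

`simulateGxEData()` reproduces the study design the method targets
without any external download, standing in for a real
multi-population whole-genome panel:

* **Genotypes.** Balding-Nichols: ancestral frequencies U(0.05, 0.5),
  population frequencies Beta-drifted with F = 0.1, genotypes
  Binomial(2, p_kj), 7 populations at the panel's sample shares
  (24/13/19/20/19/4/1%). Candidate and kinship SNP sets are disjoint by
  construction. F = 0.1 matches the global-scale differentiation of the
  panel it emulates.
* **Exposure and covariates.** Sex ~ Bernoulli(0.5), the exposure
  (optionally population-dependent to induce gene-environment
  dependence); age ~ N(50, 10) — the design says only that age is
  Normal, so location and scale are package choices.
* **Effects.** |S| = 100 main effects N(0, h2_S sigma2 / |S|) and
  |S'| = 50 GEI effects N(0, h2_S' sigma2 / |S'|); hierarchical
  scenario: S' drawn inside S (100 causal SNPs total); non-hierarchical:
  S' disjoint from S (150 total).
* **Random effect.** One draw of N(0, h2_g sigma2 K + h2_d sigma2 K_D)
  via eigendecomposition.
* **Phenotypes.** logit(pi) = logit(pi0_k) - log(1.3) Sex
  + log(1.05) Age / 10 + sum_S beta_j G_std_j
  + sum_S' gamma_j (Sex * G_std_j) + epsilon, with per-population
  baseline prevalence pi0_k ~ U(0.1, 0.9). Defaults: h2_S = 0.2,
  h2_S' = 0.1 and the low-polygenic setting (h2_g, h2_d, sigma2) =
  (0.2, 0.1, 9); the high-polygenic setting is (0.4, 0.2, 35).

With h2_S = 0.2 split over 100 SNPs, each causal main-effect SNP is
designed to explain 0.2% of the logit-scale variance. Measured
empirically, the share comes out slightly higher: under discrete
population structure the pooled variance of a column standardized by
`2 p_hat (1 - p_hat)` exceeds 1 by approximately
`(1 + 0.625 F) / (1 - 0.188 F)` (the constants are 1 - sum(w^2) x F/ ...
evaluated at the default population weights), about 8% at F = 0.1. The
same inflation affects any structured panel; tests against the empirical
share use this closed-form factor as the oracle.

What the generator does *not* emulate: linkage disequilibrium between
SNPs, admixed ancestry, and family-level relatedness beyond the
population blocks. Selection results on simulated data therefore say
nothing about the behaviour under strong local LD, where selected SNPs
tag rather than identify causal ones.

## Problem sizes used in the test suite

The packaged checks run the full pipeline at reduced scale, chosen so
each check exercises the regime it is about: the hierarchy check fits the
complete 50 x 10 default grid at n = 500, p = 2000; KKT certification
uses n = 60, p = 10 with tightened tolerances (inner 1e-10, outer 1e-12,
raised iteration caps) because certifying stationarity to 1e-4 demands a
sharper solve than selection does; variance-component recovery uses
n = 1000 with 50 replicates on block kinship (20 blocks of 50 — large
blocks keep the PQL attenuation for binary traits well inside the
tolerance, the exposure split leaves ~25-member cells for the
gene-by-environment component); the two-random-effects-versus-one
contrast runs 20 replicates at n = 800, p = 5000 with a reduced CV
protocol (8 lambda values to 0.1 lambda_max at the mid-range rho = 0.45,
2 folds), which in pilot form selects the same models as the full grid
while keeping the comparison affordable. The acceptance script measures the per-SNP variance share on
100 replicate datasets at n = 1000, since the share is scale-free and
its precision is set by the replicate count.

## Known limitations

* PQL attenuates variance components for binary traits; no bias
  correction (e.g. higher-order Laplace) is applied. At the default
  simulation scale the gene-by-environment component is frequently
  estimated at its zero boundary, in which case the two-random-effect
  model gracefully degenerates to the one-random-effect model.
* The dense end of the path (support comparable to n) is non-unique in
  p > n problems; coefficients there should be read as one element of
  the solution set.
* Lasso-type shrinkage biases retained effect estimates toward zero; the
  odds ratios in the output tables inherit that bias (no relaxed
  refitting).
* Memory is O(n^2 + np): dense kinship and genotype matrices. Sample
  sizes beyond ~20k would need sparse or low-rank kinship handling,
  deliberately out of scope.
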