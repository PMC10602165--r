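---
title: "Twin-design Mendelian randomization: models, exact simulation, and power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin-design Mendelian randomization: models, exact simulation, and power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrdoctwin)
```

## The models

Three nested covariance-structure models for pairs of twins measured on an
exposure X and an outcome Y:

* **DoC** (Direction of Causation): a bivariate ACE twin model with causal
  paths between the phenotypes. Cross-twin cross-trait covariances carry the
  information that separates X -> Y causation from Y -> X causation and from
  confounding.
* **MR-DoC**: adds a polygenic score PS1 as an instrumental variable for the
  exposure (path `b1`), and — unlike classical Mendelian randomization —
  frees the direct (pleiotropic) path `b2` from PS1 to the outcome. The
  unshared-environment correlation `re` must be fixed to 0 for
  identification.
* **MR-DoC2**: adds a second score PS2 as an instrument for the outcome
  (path `b3`), drops `b2`, and frees both causal directions (`g1`, `g2`)
  together with all three background correlations `ra`, `rc`, `re` and the
  score correlation `rf`.

Phenotypes solve the simultaneous system

    X = g2*Y + b1*PS1 + A1 + C1 + E1
    Y = g1*X + b2*PS1 + b3*PS2 + A2 + C2 + E2

with reduced form through `(I - B)^(-1)`, `B = [[0, g2], [g1, 0]]`. The ACE
residual factors follow the classical twin rules: additive-genetic factors
correlate 1 across MZ co-twins and 0.5 across DZ co-twins, shared
environment correlates 1, unshared environment 0. Polygenic scores are
themselves additive-genetic quantities, so their cross-twin correlation is 1
(MZ) and 0.5 (DZ).

A consequence taken seriously throughout the package: **MZ co-twins carry
literally identical polygenic scores.** Including both copies as observed
variables would make the MZ covariance matrix singular (two identical
variables), so the MZ group observes each score once — MR-DoC has 5 MZ and
6 DZ variables, MR-DoC2 has 6 and 8. `model_variables()` documents the
ordering; `implied_sigma()` builds both group matrices from one parameter
vector.

## Parameters, defaults, units

All parameters are on the (standardized) covariance scale of the residual
phenotypes:

| parameter | meaning | default design value |
|---|---|---|
| `g1`, `g2` | causal regression weights | 0.02 / 0.04 |
| `b1`, `b3` | instrument paths (PS1 -> X, PS2 -> Y) | 0.025 / 0.05 |
| `b2` | directional pleiotropy PS1 -> Y (MR-DoC) | 0.025 / 0.05 |
| `VA`, `VC`, `VE` | residual ACE variances per trait | 0.10 / 0.10 / 0.80 |
| `ra`, `rc`, `re` | cross-trait factor correlations | 0 / 0.2 |
| `rf` | correlation of the two scores | 0.2 (Design 3) |
| `vP1`, `vP2` | polygenic-score variances | 1 |
| `rhoX`, `rhoY` | phenotype reliabilities | 0.90 / 0.70 |

`VE = 1 - VA - VC` keeps each residual phenotypic variance at 1, so path
coefficients read approximately as correlations. Correlations are converted
internally to factor covariances (`CA = ra*sqrt(VA1*VA2)`, ...), and the
fitter estimates the covariances directly (the variance-component
parameterization); correlations are re-derived for reporting only.

The three factorial designs (`design_grid()`) cross these levels: Design 1
(DoC, 8 cells), Design 2 (MR-DoC, 32 cells), Design 3 (MR-DoC2, 64 cells,
`re = rf = 0.2` fixed). These defaults *are* the study conditions; they are
deliberately not tuning knobs.

## Exact data simulation

`exact_mvn_sample()` generates multivariate-normal records whose sample
covariance equals the model-implied population covariance to machine
precision (draws are centered, whitened by their own sample covariance, and
recolored by the target — `MASS::mvrnorm(empirical = TRUE)`). Two things
follow:

1. fitting the generating model recovers the generating parameters exactly
   (to optimizer precision), which every run verifies; and
2. the likelihood-ratio statistic of a false constraint equals the
   non-centrality parameter (NCP) of the test, so chi-square power can be
   read off a single fit pair instead of thousands of Monte-Carlo
   replicates.

Seeds only affect the raw records, never the moments: all pipeline
summaries are invariant to `master_seed`, and the tests assert this.

Measurement error with reliability `rho` is injected at the covariance
level: the phenotype diagonal is inflated by `Var * (1 - rho)/rho`, leaving
every covariance untouched. Under exact simulation this is equivalent to
adding independent record-level noise — a test checks the equivalence
against a record-level oracle — but it is deterministic.

## Fitting and power

`fit_ml()` minimizes the multigroup normal-theory discrepancy

    F = sum_g N_g [ ln|Sigma_g(theta)| + tr(S_g Sigma_g(theta)^{-1}) - ln|S_g| - p_g ]

with zero means, `N_g` = pairs per group, and the `n-1`-divisor sample
covariance. Optimization is bound-constrained quasi-Newton (L-BFGS-B,
numerical gradients with step 1e-6; on failure, restarts from a perturbed
start and from the incumbent optimum with fresh optimizer state); variance
components are bounded at 0 and boundary solutions are
reported as-is, which is appropriate here because the tested constraints
(`g1`, `g2`) are interior parameters. Convergence requires the projected
gradient below 1e-3; a failed line search at a stationary point (the normal
outcome when starting at the truth on exact data) counts as converged.
`lrt_ncp()` clips statistics within 1e-8 of zero and treats anything more
negative as an optimization failure rather than a statistic.

`power_from_ncp(ncp, df, alpha)` is the upper tail of the noncentral
chi-square at the central critical value.

### Causal specification of the fitted models

A bivariate twin ACE model is identified with any three of the five paths
connecting the traits (`g1`, `g2`, `ra`, `rc`, `re`) free. Two fitted
specifications are used:

* **Unidirectional** (`causal = "unidirectional"`, the default): `g1`,
  `ra`, `rc` free, `g2 = re = 0` — the Design 1/2 parameter lists. Every
  scenario fits DoC and MR-DoC this way, including the power study: it is
  the specification under which the bias studies are defined, and it keeps
  the `g1 = 0` test comparable across scenarios.
* **Bidirectional** (`causal = "bidirectional"`, DoC and MR-DoC only):
  `g1`, `g2`, `rc` free, `ra = re = 0` — the other identified choice of
  three free trait-connecting paths. It is exposed because fitting a
  unidirectional model to data generated by the bidirectional MR-DoC2
  process is itself a misspecification, and a user may reasonably prefer
  the bidirectional reading for the power study. The two specifications
  give markedly different power profiles (the unidirectional fit absorbs
  reverse causation and the unshared-environment confound into `g1`-hat,
  producing a large NCP offset; the bidirectional fit absorbs them into
  `g2`-hat and `rc`-hat, leaving a small NCP), so which one is "the" DoC
  power is an identification decision, not a numerical one. The package
  defaults to the unidirectional reading and leaves the other a function
  argument away.

## The five scenarios

`run_scenario()` drives the studies; all use 1000 MZ + 1000 DZ pairs and
alpha = 0.05.

* **S1** own-model generation, reliabilities 0.90 (exposure) and 0.70
  (outcome): DoC and MR-DoC underestimate `g1`; MR-DoC2's causal and
  instrument paths are untouched because the error inflates only `VE` and
  `CE`, which MR-DoC2 estimates freely.
* **S2** own-model generation with `re = -0.3 / +0.3`, fit with `re = 0`
  (MR-DoC2 estimates it): `g1`-hat moves in the direction of `re`,
  antisymmetrically to first order.
* **S3/S4** the same two perturbations with MR-DoC2 as the generating
  process and all three models fitted: biases in DoC and MR-DoC become
  larger and more widespread; MR-DoC2 recovers `g1`, `g2`, `b1`, `b3`
  exactly.
* **S5** power: per Design-3 cell, each model is fit with and without
  `g1 = 0`; the NCP difference and its chi-square power are recorded, and
  `ncp_regression()` regresses the 64 NCPs on the six varying factor values
  (main effects with intercept — constant factors are absorbed by it).

Why measurement error cannot bias MR-DoC2 but must bias the others: the
PGS-phenotype covariance block pins `g1`, `g2`, `b1`, `b3` exactly (it is
untouched by error), and the inflated phenotype block is absorbed by the
free `VE` and `CE` components. DoC and MR-DoC fix `CE = 0`, so the
re-expressed error covariance `-g1*dX - g2*dY` lands on the causal paths
instead.

## Numerical choices and degenerate inputs

* `1 - g1*g2` within 1e-10 of zero is an explicit "causal loop unit root"
  error; the optimizer penalizes `|g1*g2|` near 1.
* Non-positive-definite implied matrices raise errors naming the context;
  during optimization they are penalized, not crashed on.
* `exact_mvn_sample()` requires `n_pairs > p` (whitening is singular
  otherwise) and a positive-definite target.
* Starting values are the generating truth inside the pipeline (the
  simulation context knows it) and `variances 0.3, paths/covariances 0.01`
  otherwise. Constrained fits start from the unconstrained solution.
* NCP regressions refuse constant responses and rank-deficient designs by
  name rather than propagating `NaN`.

## What the generator does and does not emulate

Exact-data simulation reproduces *population* covariance algebra: results
are deterministic statements about model structure (bias of a misspecified
fit, non-centrality of a test), not about sampling variability. Passing
tests therefore show that the models and their likelihood machinery are
internally correct and match the documented population quantities; they do
not show robustness to finite-sample noise, non-normality, missing data,
selection, or assortative mating, none of which the generator produces.
Phenotypes and scores are multivariate normal with zero means by
construction.

## Problem sizes

The full pipeline is small by design: 104 design cells across the three
grids, two zygosity groups of 1000 pairs each, and at most two fits per
cell and model. A complete scenario runs in minutes on one CPU; the
structural Monte-Carlo oracle used by the acceptance checks draws 10^6
twin pairs per group for three representative cells.

## Known limitations

* Only two phenotypes; no multiple indicators, ordinal liabilities, or
  extended pedigrees.
* No standard errors or profile likelihoods — the exact-data design makes
  point recovery and NCPs the quantities of interest.
* The `re`-misspecification and measurement-error studies quantify bias
  under this package's fitted specifications; other identification choices
  (e.g. freeing `ra` instead of `rc` in the bidirectional fits) change the
  numbers, and the machinery exposes them rather than hiding the choice.
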