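---
title: "Phylospatial inference for cross-cultural trait data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylospatial inference for cross-cultural trait data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(galton)
```

## The problem: neighbours and relatives are not independent data points

Cross-cultural hypotheses are routinely tested by regressing one trait on
another across societies, languages or sites — tonality on humidity, cuisine
on climate, beliefs on parasite load. These regressions assume independent
observations, but cultures are not independent: neighbouring cultures share
environments and diffuse traits to one another, and related cultures inherit
traits from common ancestors (Galton's problem). Any trait whose values
cluster in space will therefore correlate with *any* environmental variable
that also clusters in space, with no causal link required. The practical
symptom is a "significant" naive regression whose residuals are themselves
spatially autocorrelated; the cure is a model in which proximity (and
optionally relatedness) is part of the covariance structure, so that the
covariate must explain variation *beyond* what location already explains.

This package implements that full workflow:

1. **Diagnose**: Moran's I on variables or model residuals, and the Mantel
   test between distance matrices.
2. **Model**: a naive GLM (`fit_glm()`) and a latent-Gaussian spatial GLMM
   (`fit_spatial_glmm()`) whose random effect has covariance built from
   great-circle distances (exponential / Matérn kernel), optionally plus a
   phylogenetic component.
3. **Decide**: `compare_models()` classifies the association as
   `spatially_robust`, `explained_by_space`, `space_revealed`, or
   `no_association`; `reanalyze()` runs the whole sequence in one call.
4. **Validate**: a synthetic-world generator (`build_world()`) that
   reproduces the false-positive mechanism with known truth, so every claim
   the package makes about error rates is checkable by simulation.

## The models

### Naive GLM

`fit_glm()` fits logistic (binomial-logit) or Gaussian-identity regression
by iteratively reweighted least squares, written in-package so that every
quantity the workflow reports (Wald standard errors from the inverse
observed information, 95% CIs using the 1.959964 normal quantile, odds
ratios, log-likelihood, AIC = 2k − 2ℓ) is explicit and testable.
Convergence is declared when the maximum absolute score drops below 1e-8 or
the relative deviance change drops below 1e-10, with a cap of 100
iterations. Perfect separation is detected two ways: a coefficient beyond
±15 while the deviance is still falling, or a deviance that collapses to
zero at convergence; both raise an error naming the offending covariate
rather than returning meaningless estimates.

### Spatial (and phylospatial) GLMM

The corrective model adds a latent field `u` with one value per site:

$$y_i \sim \mathrm{family}\big(g^{-1}(x_i^\top \beta + u_i)\big), \qquad
u \sim \mathrm{MVN}(0, \Sigma),$$
$$\Sigma = \sigma^2_s\,K_s(\rho) + \sigma^2_p\,K_p + \tau^2 I,$$

where `K_s` is the exponential (`exp(-d/ρ)`) or half-integer Matérn
correlation built from great-circle distances (IUGG mean Earth radius,
6371.0088 km), `K_p` an optional phylogenetic correlation (Brownian-motion
covariance from a tree via `ape::vcv()`, or shared-level fractions from a
hierarchical classification), and `τ²` a nugget that absorbs site-level
noise and doubles as a numerical stabilizer. Both `K` matrices are rescaled
to unit diagonal before weighting, so `σ²_s` and `σ²_p` are directly
comparable marginal variance components: if the data carry no spatial or
phylogenetic signal, those components shrink toward zero and the fit
collapses to the naive GLM (an exact identity the tests verify).

Fitting is Laplace-approximate maximum likelihood with dense linear algebra,
appropriate for the n ≤ ~1000 regime of cross-cultural datasets:

* **Inner step** — for a candidate θ = (σ²_s, ρ, τ², …), a penalized Newton
  iteration finds the joint mode of (β, u); each step solves one
  (p+n)-dimensional Cholesky system.
* **Outer step** — θ is searched on the log scale by Nelder-Mead over the
  Laplace objective
  $\ell_L = \log f(y\,|\,\hat u) - \tfrac12 \hat u^\top \Sigma^{-1}\hat u -
  \tfrac12 \log\det(\Sigma H + I)$.
  A derivative-free outer search was chosen over quasi-Newton because the
  objective's numerical gradient is noisy where the likelihood is flat in
  (σ², ρ); a forward-difference gradient is still computed at the optimum as
  a convergence diagnostic, and non-PSD proposals are rejected by a barrier
  rather than crashing.
* **Refinement step** — the joint (β, u) mode systematically shrinks β a
  little relative to the Laplace objective proper, because the
  log-determinant depends on β through the IRLS weights. After the θ search,
  β is therefore re-optimized against the true Laplace marginal (with u
  re-solved at every candidate). In simulation this removes about half of
  the attenuation of β and brings 95% Wald CI coverage from ~0.88 to ~0.95.
* **Standard errors** — the Wald covariance of β is the β-block of the
  inverse observed information of the Laplace marginal in (β, log θ)
  jointly (finite differences, with u re-solved per evaluation), so the
  uncertainty of the variance parameters propagates into the reported
  standard errors. Free parameters sitting at a boundary (a nugget at its
  floor) carry no curvature and are held fixed there; the
  conditional-on-θ̂ information is the fallback when the joint Hessian is
  ill-conditioned.
* **Gaussian family** — the Laplace approximation is exact and the fit
  equals generalized least squares with V = Σ + σ²_e I; the implementation
  is the closed form, and tests require agreement with an independently
  coded GLS solution to 1e-6.

AIC counts fixed effects plus *free* variance parameters. Significance of
the focal covariate is reported as a Wald z (primary), with a
likelihood-ratio refit available via `spatial_lrt()` (secondary) — the two
can disagree slightly because the variance components are re-estimated under
the null in the LRT.

Numerical choices worth knowing: variance parameters are optimized as logs
(positivity without constraints); `τ²` has a floor of 1e-6 when estimated
(identifiability guard when the kernel is nearly singular at coincident
points — coincident sites are legitimate input and are *never* jittered in
coordinates, only stabilized through the nugget); Cholesky factorizations
escalate a diagonal inflation from 1e-10 of the mean diagonal upward and
fail only after six decades.

### Autocorrelation diagnostics

`morans_i()` implements the cross-product statistic with the analytic null
moments (E[I] = −1/(n−1); Cliff–Ord randomization variance with kurtosis
correction by default, normality variance for cross-checks) and a
permutation null (sampled, or exhaustive for n ≤ 8 — the exhaustive mode
exists so tests can compare against full enumeration). Default weights are
inverse great-circle distance with a 1 km floor and no row standardization,
the common residual-diagnostic choice; k-nearest and kernel schemes are
available. Note that `ape::Moran.I` row-normalizes internally, so its
statistic corresponds to `spatial_weights(..., row_standardize = TRUE)` —
the package's tests pin this correspondence. Residual diagnosis uses Pearson
residuals. `mantel_test()` correlates strictly-lower-triangle entries and
permutes rows and columns jointly, one-sided (greater) by default; Moran's
test is two-sided by default since clustering and over-dispersion are both
detectable.

## The synthetic worlds

`build_world()` generates the statistical world the workflow is designed
for. Coordinates come from a uniform box or a clustered (parent–offspring)
process with Gaussian jitter applied in a local tangent plane — a
deliberate approximation, adequate for dispersion scales up to ~500 km. The
environmental covariate mixes three standardized components in stated
variance shares: a deterministic cos(latitude) gradient (humidity-like
variables are latitudinally patterned), a spatial Gaussian random field
(they are smooth but not purely latitudinal), and white noise. The outcome's
linear predictor adds a latent field drawn by Cholesky from the kernel
covariance, and optionally a Brownian trait on a coalescent tree. All
truths are retained in dot-prefixed columns that model formulas never touch
unless named explicitly. A single root seed spawns fixed per-component
streams, so e.g. the outcome draw can change while the geometry stays put.

Two presets define the package's reference conditions:

* `scenario_tone_humidity()` — n = 527 clustered sites (8 parents, 500 km
  dispersion), binary outcome with prevalence ≈ 0.44, a strong exponential
  latent field (σ²_s = 4, ρ = 2000 km, τ² = 0.2), environment shares
  0.25/0.6/0.15, and **no true effect**. Under these settings the naive GLM
  is "significant" in well over half of replicates and the residual Moran z
  is typically above 10 — the structural signature of the motivating
  false-positive, chosen to match that qualitative signature rather than
  any exact published statistic.
* `scenario_confounded()` — n = 300, fifteen clusters with an intense,
  long-range latent field (σ²_s = 16, ρ = 3000 km) and an environment that
  is almost entirely spatial (share 0.90), the workhorse for type-I-error
  experiments: the naive GLM rejects the null covariate in over half of
  replicates while the spatial GLMM stays near the nominal 5%. The cluster
  count matters: with very few clusters the effective sample for the
  variance parameters is tiny, σ²_s is badly underestimated, and even the
  spatial model's Wald test inflates (the t-versus-normal problem familiar
  from few-group mixed models); fifteen clusters keep the field estimable
  and the test calibrated.

What passing these simulations does *not* show: the generator draws the
latent field from the same kernel family the model fits (no kernel
misspecification), places sites with known cluster structure (real language
samples are spatially biased in messier ways), and makes the environment
exactly the sum of its declared components. Calibration under these
conditions is a necessary, not sufficient, condition for trusting the model
on real data.

## A worked run

```{r, eval = FALSE}
library(galton)

world <- build_world(scenario_tone_humidity(n = 300, seed = 42))
report <- reanalyze(world$data, outcome ~ env, seed = 42)
report
#> Naive model:      "significant" env effect (a false positive by construction)
#> Residual Moran:   z >> 2, strong spatial autocorrelation
#> Spatial model:    env no longer significant
#> verdict: explained_by_space
autoplot(report)
```

The false-positive-rate experiment makes the same point at scale
(`fpr_experiment(scenario_confounded(n = 300, seed = 1), replicates = 200)`),
and `scripts/acceptance.R` reruns all of it from scratch.

Real tables enter through `read_geo_table()` (CSV/TSV with configurable id,
lon, lat columns); users with the published tonality–humidity table (WALS
feature 13A with humidity scores) can reproduce the motivating reanalysis
directly with `reanalyze(path, tonality ~ humidity)` — the naive fit,
residual diagnosis, spatial refit and verdict come back in one report.

## Problem sizes, runtime, and defaults

The heavy simulations in the test-suite and acceptance script use n = 100
(iid calibration, 500 replicates), n = 300 (confounded worlds, 200
replicates; recovery, 100 replicates) — sizes at which a dense-matrix
Laplace fit takes a couple of seconds and the full experiment batteries run
in minutes on one CPU. The spatial GLMM itself is practical to roughly
n ≈ 1000; beyond that, dense Cholesky costs dominate and sparse or
nearest-neighbour approximations (out of scope here) are the right tools.

Key defaults, and why: Earth radius 6371.0088 km (IUGG mean; overridable);
Moran weights inverse-distance with d_floor = 1 km (coincident-point
guard); permutation count 999; α = 0.05; classification covariance uses
equal per-level increments (the cited idea comes without a formula; equal
increments is the least-informative choice and is configurable by editing
the classification's levels); Matérn smoothness restricted to ν ∈ {0.5,
1.5, 2.5} (closed forms, no Bessel evaluations — ν is rarely identifiable
from a few hundred points anyway).

## Known limitations

* Wald inference for β ignores uncertainty in the variance parameters; the
  refinement step makes coverage acceptable at n = 300, but for small n or
  very strong fields the CIs remain slightly optimistic.
* The Laplace approximation is known to attenuate binary-outcome effects
  somewhat even after refinement (median β̂ ≈ 0.73 at a true 0.8 in the
  recovery conditions above); where unbiasedness matters more than runtime,
  MCMC or quadrature-based fits are preferable.
* `ρ` and `σ²_s` are only weakly jointly identifiable when the range is
  comparable to the domain size; the reported components should be read as
  a pair (their product is what the data pin down), and a profile over a
  fixed ρ grid is the fallback for flat likelihoods.
* SAR/CAR autoregressive models, Conley standard errors, and spatial
  structural-equation models are intentionally out of scope.
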