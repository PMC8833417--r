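---
title: "Methods: two-stage density surface modelling of pellet-group surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage density surface modelling of pellet-group surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelletdsm)
```

## The estimation problem

Dung pellet-group counts on line transects are a cheap, indirect index of
deer abundance: the density of pellet groups along environmental gradients
is a proxy for the relative abundance of the animals that deposited them.
Two obstacles stand between raw counts and a density map. First, detection
is imperfect and decays with perpendicular distance from the transect line,
at a rate that differs between observers and ground-cover types. Second,
transects cover a vanishing fraction of the landscape, so mapping requires a
spatial regression onto environmental covariates — and an honest account of
where that regression extrapolates beyond the data.

`pelletdsm` implements the classical two-stage answer:

1. **Detection stage.** A detection function $g(x; z)$ — the probability of
   detecting a pellet group at perpendicular distance $x$ given covariates
   $z$ — is estimated from the truncated distances by maximizing the
   conditional likelihood
   $\prod_i g(x_i; z_i) / \mu(z_i)$, with
   $\mu(z) = \int_0^w g(x; z)\,dx$ the effective strip half-width. Keys are
   half-normal, $\exp(-x^2/2\sigma^2)$, and hazard-rate,
   $1 - \exp(-(x/\sigma)^{-b})$ with $b > 1$; both satisfy $g(0) = 1$.
   Covariates act log-linearly on the scale,
   $\sigma(z) = \exp(\beta_0 + \sum_k \beta_k z_k)$ (multiple-covariate
   distance sampling). Adjustment series (cosine, Hermite, simple
   polynomial, distances scaled by $w$) are available for covariate-free
   fits only. Model choice is by AIC; adequacy by a Cramér–von Mises test
   with a parametric-bootstrap p-value.

2. **Density stage.** Each detection contributes $1/p(z_i)$, with
   $p(z) = \mu(z)/w$, to its segment's Horvitz–Thompson abundance
   $\hat n_j$. These are modelled as
   $\log E[\hat n_j] = \log A_j + \beta_0 + \sum_k f_k(z_{jk})$, a penalized
   additive model with thin-plate regression spline smooths, the strip area
   $A_j = 2 w l_j$ as offset, and a tweedie or negative-binomial response.
   Backward selection removes smooths until all approximate p-values fall
   below $\alpha$; families are compared by AIC, percent deviance explained
   and quantile-quantile plots of deviance residuals.

Predictions on a regular grid carry a delta-method CV: the detection-stage
CV (delta method over the detection parameters using the
observed-information covariance) and the model-stage CV (standard error of
the linear predictor, the small-error CV of a lognormal mean) combine in
quadrature, $\mathrm{cv} = \sqrt{\mathrm{cv}_\mathrm{det}^2 +
\mathrm{cv}_\mathrm{gam}^2}$. Extrapolation is assessed with ExDet (NT1/NT2
against the reference covariate hull and covariance) and the percentage of
data nearby (%N, Gower-distance neighborhoods); cells that extrapolate or
lack support are masked before any downstream use.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `truncation_m` | 1.5 | m | right-truncation of distances (≈5% of field data discarded) |
| `min_group_detections` | 70 | — | minimum detections per pooled observer group |
| `buffer_radius_m` | 500 | m | covariate summary disk, a circularized monthly home range |
| `r_threshold` | 0.7 | — | absolute Pearson correlation triggering covariate removal |
| `alpha` | 0.05 | — | smooth-term retention level in backward selection |
| `nearby_threshold_pct` | 5 | % | minimum %N support for a valid prediction |
| `min_valid_fraction` | 0.5 | — | minimum valid-cell share for a district to enter validation |
| `grid_cell_km` | 1 | km | prediction cell edge |
| `k` (per smooth) | 10 (6 in the bundled pipeline) | — | TPRS basis dimension |

The detection optimizer is quasi-Newton (BFGS) from scale starts
$\sigma_0 \in \{w/4, w/2, w\}$ with a relative likelihood tolerance of
1e-10; $\mu(z)$ uses the half-normal closed form where available and
adaptive quadrature with absolute tolerance 1e-8 otherwise. The fitted CDF
used by the goodness-of-fit test and the bootstrap sampler is a 2001-point
cumulative trapezoid per unique scale, far below the resolution of the
$W^2$ statistic. The hazard shape is parameterized as $b = 1 + e^\theta$ to
enforce $b > 1$; adjusted detection functions are rejected if negative or
increasing anywhere on a 100-point grid.

## What the synthetic generator emulates

No public survey data exist for this design, so the package ships a
generator whose defaults mirror the study conditions: smoothed-Gaussian
covariate fields with chosen autocorrelation scales (softmax-renormalized
for compositional families, so land-cover fractions sum to one),
a log-linear additive truth surface in pellet groups per m², stratified
designed surveys (200-m west–east transects, 75% of effort in woodland,
25% in open areas) and plot-centered undesigned transects (start points
uniform within 30 m of the plot center), an inhomogeneous Poisson pellet
process on each strip, and distance- and observer-dependent thinning
through the same half-normal/hazard-rate keys the estimator fits. Default
generating values — hazard-rate with $\sigma_0 = 0.5$ m, $b = 2.5$,
observer scale factors 0.75–1.25, truth intercept $\log(0.008)$ pellet
groups per m² (several thousand per km², the magnitude reported for roe
deer) — were fixed once as field-realistic and are not tuned per analysis.

The generator deliberately omits: pellet deposition and decay dynamics
(pellet-group intensity itself is the estimand), animal movement,
responsive movement to observers, spatial autocorrelation in the residual
process beyond what the covariates induce, and any geodesy (planar meters,
axis-aligned grids). Passing tests therefore demonstrate that the
estimation machinery recovers a known generating process of this ideal
form — not that field data meet these assumptions.

## Design choices where the method was genuinely open

- **Observer grouping.** Only the constraints "pooled by effort" and "at
  least 70 detections per group" are standard. The package sorts observers
  by descending total effort, greedily accumulates groups to 70 detections
  and merges a trailing undersized group into its predecessor: fully
  deterministic and reproducible from the effort table alone.
- **Cramér–von Mises weighting.** The unweighted $W^2$ with a
  parametric-bootstrap p-value (≥499 resamples, refitting the model on
  each resample) is used; distance-sampling software sometimes reports a
  weighted variant whose weights are not standardized across
  implementations.
- **Tweedie power and NB dispersion.** Both are profiled continuously
  alongside REML smoothness selection (`mgcv::tw()`, `mgcv::nb()`), rather
  than over a discrete grid — same behavior, better resolution.
- **Non-integer responses under the negative binomial.** Horvitz–Thompson
  abundances are not integers; they are rounded for the NB candidate with
  a warning. The tweedie candidate, which handles continuous positive data
  natively, is the intended primary family.
- **Backward-selection ties.** Equal p-values drop the smoother with the
  larger effective degrees of freedom first.
- **Cell-in-disk rule.** A grid cell belongs to a 500-m buffer iff its
  center lies within the radius of the segment centroid — the common
  zonal-statistics convention, and exactly what the brute-force test
  oracles enumerate.
- **Collinearity resolution.** Conflicting pairs are processed in
  descending $|r|$, the lower-priority member dropped, correlations
  re-checked after each drop; the priority list encodes ecological
  relevance (climate drivers such as winter mean temperature ahead of
  derived terrain variables).
- **Discard rule.** Two readings circulate: discard only univariate cells
  with %N < 5, or keep only analogue/combinatorial cells with %N ≥ 5. The
  stricter form is the default (`rule = "strict"`), the permissive one is
  available as `rule = "univariate_only"`.
- **District geometry.** Synthetic management districts are Voronoi cells
  around random seeds; nearest-seed assignment of cell centers is then
  identical to cell-center-in-polygon assignment. The coverage filter is
  boundary-inclusive at exactly 50%.
- **CV composition.** Published totals for two-stage CVs are not always
  reproducible from their printed components by root-sum-of-squares
  (e.g. components 0.04 and 0.25 imply 0.2532, and 0.04 with 0.16 cannot
  yield a total below 0.16). The package always uses
  $\sqrt{\mathrm{cv}_1^2 + \mathrm{cv}_2^2}$.

## Degenerate inputs and numerical corner cases

Empty observation tables truncate to empty with a warning; surveys with
fewer total detections than one group's minimum collapse to a single
observer group with a warning. Zero-variance covariates are dropped from
the collinearity screen and excluded from Gower distances, each with a
warning. A singular ExDet reference covariance is ridge-regularized
(factor 1e-8 of the mean diagonal) with a warning. Smooth basis dimensions
are capped below the number of distinct covariate values. Non-converged
detection fits are excluded from AIC selection; a failed backward-selection
refit returns the previous model with a warning.

## Problem sizes

The bundled end-to-end pipeline runs on an 8 × 8 km landscape at 200-m
resolution with 256 transects (51.2 km of effort, roughly 300 detections),
1-km² prediction cells, and both response families — a few seconds of
compute. The test suite exercises parameter recovery at n = 2000 distances,
Horvitz–Thompson bias over 200 replicate surveys, key-function and
term-selection recovery over 50 replicates each, bootstrap GOF calibration
over 100 replicates, and exact brute-force agreement of the extrapolation
metrics on 50 × 200-point instances; these sizes were chosen to keep Monte
Carlo error comfortably below each test's tolerance.

## Known limitations

- The detection stage offers line transects only (no points, no
  left-truncation, no double-observer models).
- The density stage fits independent-error additive models; residual
  spatial autocorrelation, tensor interactions and soap-film bases are out
  of scope.
- Per-cell CVs propagate coefficient uncertainty at fixed smoothing
  parameters; smoothing-parameter uncertainty and posterior simulation are
  not included.
- Zonal statistics are cell-center based, not area-weighted; reprojection
  and CRS handling are absent by design (synthetic planar world).
- Pellet-group density is never converted to animal density: that would
  require defecation and decay rates, which are habitat- and
  climate-specific and outside the package's scope.

## A worked pipeline call

```{r pipeline, eval = FALSE}
res <- run_pipeline(pipeline_config(seed = 1))
glance(res$detection)       # selected key, AIC, p-bar with CV
res$comparison              # tweedie vs negative binomial, delta AIC
tidy(res$dsm)               # retained smooths with edf and p-values
res$class_summary           # analogue / combinatorial / univariate shares
res$correlation             # Spearman rho against district harvest density
plot_prediction_map(res$cells)
```
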