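---
title: "Models and methods behind stringair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stringair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`stringair` links the strictness of COVID-19 lockdown policies to
modelled changes in urban air pollution and to the short-term mortality
burden those changes imply. This vignette is the package's own account of
the models it fits, the choices that were genuinely open, and what its
synthetic-data experiments do and do not demonstrate.

## The Stringency Index

Nine ordinal policy indicators (school closing C1, workplace closing C2,
cancellation of public events C3, gathering restrictions C4, public
transport closure C5, stay-at-home requirements C6, internal movement
restrictions C7, international travel controls C8, and public information
campaigns H1) are each standardized by their maximum level, and the SI is
100 times their mean. The implementation is deliberately this plain mean
— not the OxCGRT composite with flag-variable corrections — because the
plain mean is the construction the analysis this package operationalizes
describes, and it yields the exact identity

```
9 * si = 8 * si_without(k) + 100 * z_k
```

for every component `k`, which the test suite asserts on random panels.
Policy levels are national: all cities of a country carry one series.
Missing indicator data is a hard validation error, never imputed, because
silently imputed policy levels would contaminate the leave-one-out SI
used by the decomposition model.

## The exposure-response model

The pollutant change (Lockdown − BAU, µg/m³) for city *i*, day *t* is

y_it = f(x_it; β + b_i) + γ_1i DOW_t + γ_2 NDVI_i + γ_3 BuiltUp_i + ε_it

with a shared natural cubic spline `f` (4 df) of the SI and
city-specific spline-coefficient deviations `b_i`.

**Anchoring instead of an intercept.** No pollutant change is expected
while there is no policy response, so the model carries no intercept.
Operationally the spline basis is shifted by its value at SI = 0, making
every basis column exactly zero there; predictions at SI = 0 are exactly
zero with zero-width bands, and the test suite asserts this. The
anchoring is a construction choice: the intent (remove the intercept) is
fixed, the mechanism was open, and subtracting the basis row at zero is
the minimal one.

**Knots.** The three interior knots sit at the 25/50/75 % quantiles of
the pooled SI over all city-days, because `f` is shared across cities
(per-city knots would break the shared basis). First-wave SI
distributions pile up at 0 (the pre-response weeks) and at the plateau
level, so a quantile can collide with a boundary knot or another knot;
the spec then falls back to quantiles of the interior (0 < SI < max)
values, and only if still degenerate to equally spaced knots. Fewer than
five distinct SI values is an error: the exposure-response is not
estimable from such a design.

**Day-of-week effects** are a 7-level factor per city under a per-city
sum-to-zero constraint (six free contrasts). Without that constraint the
city DOW effects would absorb exactly the intercept the model removed;
this is the minimal identifiable coding.

**Covariates.** NDVI and built-up share are z-scored across cities
before entering the model; their scale is otherwise arbitrary and
z-scoring keeps the vague priors comparable across coefficients.

**Spatial structure.** Each of the four coordinates of `b_i` is an
independent zero-mean Gaussian field over cities with Matérn covariance
(smoothness ν = 1, the 2-D default of SPDE-based toolchains) evaluated on
great-circle (haversine) distances in km. With at most a few dozen
cities the exact dense Gaussian process is trivial, so no mesh-based SPDE
approximation is used: the model is the Matérn GP itself. Each field has
its own range and marginal standard deviation under a shared
penalized-complexity prior: P(range < range₀) = α_range and
P(sd > sd₀) = α_sd, with defaults range₀ = 500 km, α_range = 0.5,
sd₀ = 1 µg/m³ (per basis unit), α_sd = 0.05 — i.e. a prior median range
of 500 km and a 5 % prior probability that a field's spread exceeds
1 µg/m³. These hyperprior values are configuration, not estimates; the
PC-prior tail identities are verified by quadrature in the tests.

**"Flat" priors.** Unstructured coefficients (β, DOW contrasts, γ₂, γ₃)
get Normal(0, 10⁶ · var(y)) priors rather than strictly improper flat
priors — a deviation chosen for engine stability that is numerically
indistinguishable at the data's scale.

## The inference engine

Given the hyperparameters θ = (residual sd; range_k, sd_k per field) the
model is linear-Gaussian, so the coefficient layer is integrated out in
closed form and a random-walk Metropolis sampler explores only log θ
(9 dimensions, 11 with a policy term). Each iteration costs one Cholesky
factorization of the coefficient precision; the proposal scale adapts
during burn-in towards ~25 % acceptance. Retained hyperparameter draws
are thinned evenly from the post-burn-in chain; at each, the exact
conditional multivariate-normal coefficient draw is taken. Point
estimates are Rao-Blackwellized: the analytic conditional means are
averaged over hyperparameter draws, which removes the O(1/√n_draws)
Monte-Carlo noise that draw averaging would add (material in the
noiseless identifiability test, harmless elsewhere). Intervals use the
empirical 2.5/97.5 percentiles of the draws.

Numerical safeguards: the Matérn correlation matrix carries a 1e-8·sd²
diagonal jitter; the residual sd is floored at 1e-3 times the sample sd
of the response so that noiseless synthetic data cannot push the
likelihood precision past double-precision Cholesky range; a
non-finite or non-positive-definite proposal is simply rejected.

Convergence is reported, not assumed: a split-half potential-scale-
reduction statistic per hyperparameter plus acceptance-rate bounds set a
`converged` flag, and fits warn when it is false. The spatial standard
deviations of weakly informed fields mix slowly, so the flag is
deliberately conservative; the parameter-recovery experiments below
measure what matters (curve error and interval coverage) directly.
Default chain settings (4000 iterations, 1000 burn-in, 400 draws) fit a
10-city world in ~3 s and a 47-city × 182-day world in ~30 s.

## The policy decomposition

Each indicator is fitted in its own model with the leave-one-out SI
`x'`: y = (α + a_i) z + f(x'; β + b_i) + … . The nine fits are fully
independent (fresh hyperparameters each), mirroring a
separate-models-per-policy design; `x'` keeps the plain scale
100 × mean-of-eight (the alternative — rescaling x' back to 0–100 by
9/8 — would only rescale the spline axis, not the fit). The spline knots
for `x'` are re-derived from the `x'` distribution, since it is a
different variable; this was left open by the design and re-deriving is
the choice consistent with "knots at quantiles of the predictor". A
policy that never activates (z ≡ 0) is a degenerate-design error, not a
silent zero coefficient. Because the first wave implemented most
policies nearly simultaneously, z and x' are strongly collinear in
realistic panels; the package does not attempt to break this
collinearity, it reports the honestly wide intervals (a two-scenario
test asserts that perfect lockstep widens the α interval relative to
staggered implementation).

## The health impact assessment

Daily attributable deaths are d_it = m_i · p_i · (1 − e^{−ξ y_it}),
applied to the *observed* panel differences, independent of any fitted
SI model (a model-predicted variant would propagate regression error
into the burden and is intentionally not the default). Conventions fixed
here because they rescale every burden:

- **Crude death rate timescale.** `m_i` is stored as an annual rate and
  converted to daily baseline deaths as `m_annual / 365.25 · p`. The
  timescale is otherwise unstated in this literature's tables; annual is
  the Eurostat convention.
- **Risk coefficients.** ξ = log(RR)/increment and
  se = (log(hi) − log(lo))/(2·1.96·increment) from a published RR and
  95 % CI at a reference increment (usually 10 µg/m³). The package ships
  `default_risks()` placeholders in the range of multi-country
  time-series studies, clearly flagged; they are configuration.
- **Monte-Carlo.** 1000 draws ξ ~ N(ξ̂, se²); one draw per iteration is
  shared across all cities, which induces the correlated city intervals
  a shared risk coefficient implies (and makes the grand-total interval
  wider than independent-city draws would). Percentiles use the
  inclusive linear-interpolation convention (R type 7). The point
  estimate is computed at ξ̂, not at the draw mean. City totals in the
  point-estimate and Monte-Carlo paths use the same summation order, so
  a zero-se coefficient collapses intervals onto the point estimate
  bit-exactly.
- No multi-pollutant overlap correction is attempted: burdens are
  reported per pollutant and partially overlap.

## The synthetic-data generator

The generator emulates the study design so the pipeline can be tested
against a known truth: cities in a Europe-like bounding box with
log-uniform populations (1e5–1e7), uniform annual crude death rates
(0.008–0.012), and NDVI/built-up covariates; per-country policy
trajectories that sit at zero through February, jump stepwise to
at-or-near-maximum levels at a country-specific onset in early-to-mid
March (SI plateau roughly 70–90, matching the "jump to around 75 %"
shape of first-wave trackers), plateau, and relax stepwise from
mid-May; and pollutant panels generated from exactly the additive
structure the model assumes, with spatially correlated spline deviations
(Matérn, default range 600 km, sd 1 µg/m³), sum-to-zero DOW effects
(sd 0.3 µg/m³), and Gaussian residuals (default 2 µg/m³ — chosen as
realistic for daily NO₂ differences; the source analysis reports no
residual scale, so this is a testability choice, not a calibration).
The default fixed spline coefficients give a smooth negative
exposure-response reaching roughly −8 µg/m³ at high SI, comparable to
large-city NO₂ declines.

What passing tests therefore show: the estimation machinery recovers
curves, policy effects and intervals from data *with the model's own
structure* at the study's size. What they do not show: robustness to
chemistry-driven non-linearity (e.g. ozone titration), meteorological
confounding, non-Gaussian residuals, or policy-timing endogeneity — none
of which the generator emulates.

## Experiment sizes in the shipped checks

The test suite and `scripts/acceptance.R` run the exposure-response
recovery at the full study size (47 cities × 182 days; RMSE of the
recovered fixed-effect curve ≤ 20 % of the curve's range, 95 % bands
covering the truth at ≥ 85 % of SI grid points), the policy recovery and
20-replicate null calibration at 10 cities, and the replicate coverage
experiment for β at 10 cities × 60 days with 20 replicates — sizes
chosen so the whole suite completes in a few minutes while keeping the
recovery experiments at or near the scales that matter.

## Known limitations

- The engine's `converged` flag is conservative for weakly identified
  spatial hyperparameters; long-range/low-sd fields are only weakly
  constrained by ≤ 50 sites, and their posteriors mix slowly.
- The fixed-effect curve is only identified relative to the zero-mean
  Gaussian-process prior on the city deviations: with few, spatially
  correlated cities, part of a common shift can sit in either β or the
  fields, and the β bands widen accordingly.
- Residual variance is shared across cities (configurable assumption;
  the source analysis is ambiguous between shared and city-specific).
- Exposure enters the burden formula same-day; no lag structure.
- The shipped relative risks are placeholders, and burdens inherit
  whatever risk values the user supplies.
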