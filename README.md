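# stringair

Lockdown policy stringency, air-pollution change, and attributable
mortality in European cities.

During the first COVID-19 wave (February–July 2020), European governments
rolled out containment policies of very different timing and strictness,
and modelled air quality shows the resulting drop in pollutant
concentrations relative to a business-as-usual (BAU) counterfactual run
under identical meteorology. `stringair` implements, as a tested and
reusable pipeline, the statistical machinery that links the two and
prices the health consequences:

1. **Stringency Index (SI).** The 0–100 composite of nine standardized
   policy indicators (OxCGRT-style C1–C8 plus H1),
   `SI = 100 × mean(level_k / max_k)`, together with its leave-one-out
   variants `x'` used when a single policy is modelled explicitly.
2. **Spatially structured exposure–response model.** For city *i*, day
   *t*, the pollutant change (Lockdown − BAU, µg/m³) is modelled as

   ```
   y_it = f(x_it; β + b_i) + γ_1i DOW_t + γ_2 NDVI_i + γ_3 BuiltUp_i + ε_it
   ```

   where `f` is a natural cubic spline of the SI with 4 degrees of
   freedom (knots at the 25/50/75 % quantiles of the pooled SI), anchored
   so that no policy response implies no pollutant change (the model has
   no intercept); the city-level spline deviations `b_i` carry, coordinate
   by coordinate, a Matérn Gaussian-process prior over great-circle
   distances with penalized-complexity (PC) priors on range and standard
   deviation; day-of-week effects are city-specific and sum to zero.
   Inference is a collapsed Metropolis sampler over the hyperparameters
   with the Gaussian coefficient layer integrated out analytically.
3. **Per-policy decomposition.** Each indicator `z_it` (standardized to
   [0, 1]) is fitted in its own model `y_it = (α + a_i) z_it + f(x'_it; β
   + b_i) + …`, where `α + a_i` is the effect of the policy's maximum
   level and the `a_i` are spatially structured like the `b_i`.
4. **Health impact assessment.** Daily attributable deaths follow
   `d_it = m_i · p_i · (1 − exp(−ξ y_it))` with `m_i` the crude death
   rate (annual, converted to daily), `p_i` the population, and `ξ` the
   per-µg/m³ log-relative-risk from published multi-country studies;
   uncertainty comes from 1000 parametric Monte-Carlo draws of
   `ξ ~ N(ξ̂, se²)` with empirical 2.5/97.5 percentiles. Negative values
   are avoided deaths.

Because the source concentration fields (CAMS ensemble scenarios) and the
policy database are not shipped anywhere, the package includes a
first-class synthetic-data generator (`generate_cities()`,
`generate_policy_panel()`, `generate_pollution_panel()`) that emulates
the study design with a known ground truth, so every downstream stage is
testable end to end.

## Worked example

```r
library(stringair)

cities   <- generate_cities(10, seed = 1)
policies <- generate_policy_panel(cities, seed = 2)   # Feb 1 - Jul 31 2020
si       <- compute_si(policies)
truth    <- synthetic_truth(cities, seed = 3, residual_sd = 2)
panel    <- generate_pollution_panel(cities, si, truth, "NO2")

fit <- fit_pollution_model(panel, si, cities,
                           settings = engine_settings(seed = 4))
glance(fit)
#> # A tibble: 1 × 6
#>   pollutant n_cities n_draws residual_sd acceptance_rate converged
#>   <chr>        <int>   <int>       <dbl>           <dbl> <lgl>
#> 1 NO2             10     400        2.01           0.247 TRUE

predict_curve(fit, seq(0, 80, 20))
#> # A tibble: 5 × 5
#>      si city_id estimate    lo     hi
#>   <dbl> <chr>      <dbl> <dbl>  <dbl>
#> 1     0 average     0     0     0
#> 2    20 average    -2.12 -4.10 -0.690
#> 3    40 average    -2.62 -3.80 -1.74
#> 4    60 average    -3.55 -4.09 -3.11
#> 5    80 average    -5.59 -6.32 -4.96
```

The curve is the posterior of the shared exposure–response `f`: anchored
at zero by construction, then a deepening decline (µg/m³) as policies
tighten, reaching about -5.6 µg/m³ at SI = 80, with 95 % credible bands;
the `converged` flag reports the sampler's own split-chain diagnostic,
which is deliberately conservative for the weakly identified spatial
hyperparameters. `predict_at_si(fit,
80)` gives the same quantity per city, `autoplot(fit)` draws the
city-and-average curve figure.

The burden step prices the simulated concentration changes:

```r
burden <- mc_uncertainty(panel, cities,
                         coeff = default_risks()[1, ],  # placeholder RR
                         n_mc = 1000, seed = 42)
burden
#> Attributable-mortality burden (NO2)
#>   cities: 10  city-days: 1820
#>   total: -195.7 (-230.9; -158.2), n_mc = 1000
make_report(list(burden), cities, si)   # Table-1-style city x pollutant report
```

About 196 avoided deaths are attributed to the simulated NO2 decline
across the ten synthetic cities over the six months, with a 95%
Monte-Carlo interval of (-231; -158). The shipped relative risks in
`default_risks()` are placeholders for pipeline demonstration —
substantive analyses must supply literature values through
`rr_to_xi()`.

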