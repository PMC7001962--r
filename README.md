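# wheatrisk

Adverse-weather risk assessment for winter wheat under baseline and
climate-change scenarios, for agro-climatologists and crop modellers who
need event *probabilities* — not just mean responses — at site scale.

Rare damaging events (a −20 °C night on bare soil, a 60-day waterlogged
winter, three 35 °C days during grain filling) cannot be counted reliably
in a 30-year record. wheatrisk takes the standard route around that: fit a
stochastic weather generator to the site climate, simulate 300 years per
scenario, spin the soil model up for 50 years, and evaluate everything on
the remaining 250 crop seasons. Climate scenarios enter as monthly change
factors (ΔTmax, ΔTmin, precipitation ratios) from an ensemble of climate
models; results are reported as ensemble medians and ranges and can be
interpolated to maps by inverse distance weighting.

The pipeline:

* **Weather generator** — first-order Markov wet/dry chain, gamma wet-day
  amounts, wet/dry-conditioned AR(1) temperatures, sunshine fraction;
  exact change-factor perturbation algebra (expected monthly
  precipitation scales exactly by the ratio).
* **Forcing** — Ångström–Prescott sunshine→radiation, daily FAO-56
  Penman–Monteith reference evapotranspiration.
* **Soil** — two-layer water balance with degree-day snow, preferential
  flow and daily mass-balance closure below 10⁻⁶ mm.
* **Phenology** — thermal time above a base temperature from a fixed
  20 October sowing: sowing → emergence → anthesis → maturity.
* **Seven event detectors** — frost without snow (tmin ≤ −20 °C, < 1 cm
  snow), late frost after de-hardening (tmin ≤ −2 °C), extremely wet
  early season (> 60 days at field capacity, sowing→anthesis), lodging
  risk, grain-filling heat (tmax > 35 °C), adverse sowing and harvest
  conditions — each a per-season boolean, reported as the fraction of
  retained years.
* **Crop stress indices** — paired runs of a radiation-use-efficiency
  crop model give potential (Y), water-limited (Yw), drought-sensitive
  (Ywd) and heat-sensitive (Ywh) yields, hence

      HSI = 1 − Ywh/Yw    DSI = 1 − Ywd/Yw    WSI = 1 − Yw/Y

  with means and 95th percentiles (HSI95, DSI95, WSI95: the
  one-in-twenty-year loss).

Synthetic facilities (`synthetic_site_climatology()`,
`make_synthetic_ensemble()`) provide UK-like sites and a 16-member
pseudo-GCM ensemble spanning winter precipitation changes of −10%…+40%,
summer ±30% and 0.2–3.0 °C warming, so the whole pipeline runs and tests
without proprietary station data.

## Worked example

One site, baseline climate, the full chain:

```r
library(wheatrisk)

east <- synthetic_site_climatology("east", latitude = 52, variant = "default")
series <- compute_forcing(generate_series(east, n_years = 300, seed = 42))
soil <- run_water_balance(series, soil_profile("default180"))
pheno <- season_phenology(series)
retained <- pheno[pheno$harvest_year > 50, ]

event_probability(detect_adverse_events(series, soil, retained))
#>              event probability n_years
#> 1    frost_no_snow       0.000     250
#> 2       late_frost       0.024     250
#> 3 wet_early_season       0.000     250
#> 4     lodging_risk       0.000     250
#> 5   grainfill_heat       0.000     250
#> 6   adverse_sowing       0.000     250
#> 7  adverse_harvest       0.004     250

yields <- simulate_yield_set(series,
                             run_water_balance(series, soil_profile("hafren177")),
                             retained)
compute_stress_indices(yields)
#> <stress_indices> 250 years
#>   HSI: mean 0.001, 95th percentile 0.000
#>   DSI: mean 0.060, 95th percentile 0.474
#>   WSI: mean 0.070, 95th percentile 0.186
```

Reading it: in 250 simulated seasons at this eastern site, deep frost on
bare soil, waterlogging, lodging-grade rain and grain-filling heat never
occur; a late frost after a warm spell hits 2.4% of years and a blocked
harvest window 0.4%. Heat around anthesis is negligible (HSI ≈ 0); drought
around flowering costs 6% of yield on average but 47% in the worst year in
twenty (DSI95); season-long water limitation costs 7% on average. Mean
anthesis falls on day-of-year 165 (mid June) and the unstressed yield is
7.9 t/ha. A full factorial over sites × ensemble members, with ensemble
summaries and failure logging, is one call: `run_experiment()` on an
`experiment_config()` (or a YAML file via `read_experiment_config()`; see
`inst/extdata/example-config.yaml`).

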