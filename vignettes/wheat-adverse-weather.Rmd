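---
title: "Modelling adverse-weather risk for winter wheat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling adverse-weather risk for winter wheat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

wheatrisk estimates how often, and how severely, adverse weather harms
winter wheat at a site, under a baseline climate and under
climate-model-perturbed scenarios. Because the events of interest are rare
(deep frost, multi-day heat, a 60-day waterlogged winter), probabilities
cannot be estimated from a 30-year observed record directly. The pipeline
therefore fits a stochastic weather generator to the site's climate,
simulates 300 structurally identical years per scenario, discards the first
50 as spin-up, and evaluates event detectors and a daily crop model on the
remaining 250 crop seasons. This vignette documents each model, its
assumptions, the tunable parameters, and the limits of what the synthetic
test-bed can demonstrate.

## The weather generator

Daily weather is simulated with a Richardson-type generator, the standard
structure for site-scale stochastic weather simulation:

* **Occurrence.** Wet/dry status follows a first-order two-state Markov
  chain with monthly transition probabilities `p_wd` (wet after dry) and
  `p_ww` (wet after wet). A day is wet when precipitation is at least
  0.1 mm.
* **Amounts.** Wet-day precipitation is gamma distributed with monthly
  shape and scale fitted by the method of moments. The gamma is a standard
  choice for the strong right skew of daily rainfall.
* **Temperature.** Daily tmax and tmin are drawn from monthly normals
  conditioned on wet/dry status (wet days have cooler maxima and milder
  minima). Their standardised residuals share a day-to-day AR(1)
  autocorrelation (`temp_ar1`, default 0.6 — typical for mid-latitude
  daily series) and a cross-correlation (`temp_cross_cor`, default 0.8).
  On the rare day the sampled pair inverts, tmax and tmin are swapped, so
  the invariant tmax ≥ tmin holds by construction; with the default
  parameters the swap probability is below 1% even for the narrowest
  wet-day winter temperature gap, so the induced bias on monthly means is
  an order of magnitude below the Monte Carlo noise at the test scales.
* **Sunshine.** The sunshine fraction (bright hours / astronomical
  daylength) is drawn from wet/dry-conditioned normals truncated to
  [0, 1]: wet days are much duller, which is what couples radiation to the
  rainfall process.

The calendar has 365 days in every year (29 February is dropped on
import), so multi-year day counting and season windows need no leap logic;
the climatological effect is negligible.

Two properties of the implementation are load-bearing for the tests and
for paired experiments:

1. **Determinism.** Identical (climatology, years, seed) gives a
   bit-identical series.
2. **Coupled perturbations.** The RNG consumption pattern does not depend
   on parameter values, so a change-factor run under the same seed reuses
   the baseline's wet-day pattern and rescales the very same gamma draws.
   A +15% winter-rainfall member therefore produces precipitation that is
   day-for-day 1.15 times the baseline in the scaled months, which turns
   directional climate-response checks into near-deterministic paired
   comparisons.

### Change factors

Climate-model scenarios enter as monthly change factors: additive shifts
of mean tmax and tmin and multiplicative precipitation ratios, plus the
scenario CO2 concentration carried as metadata (the crop model applies no
CO2 physiology, so CO2 never affects results). Shifting the wet- and
dry-day means by the same amount and multiplying the gamma scale means
the expected monthly precipitation scales *exactly* by the ratio while
occurrence, skewness shape and temperature variances stay fixed. Changes
to variability, spell lengths or extreme-value tails are deliberately not
represented: only the monthly means are perturbed, which mirrors the
information typically taken from coarse global-model output, and it keeps
the perturbation algebra exact and testable.

`make_synthetic_ensemble()` emulates a 16-member mid-century ensemble for
a high-emissions pathway: annual-mean warming uniform in 0.2–3.0 °C with
summer amplification, winter precipitation change in −10%…+40% and summer
change within ±30%, interpolated between the seasonal peaks by cosine
half-waves so each month stays inside its season's envelope. The first two
members are pinned to the wet and dry winter extremes so range maps have
designated end-members.

## Radiation and evapotranspiration

Sunshine hours convert to solar radiation through the Ångström–Prescott
relation `Rs = (a + b·n/N)·Ra` with the conventional defaults a = 0.25,
b = 0.50 (site-specific fitted coefficients can be supplied). `Ra` and
daylength come from standard solar geometry; the computation refuses
polar latitudes where the sunset hour angle degenerates.

Reference evapotranspiration uses the full daily Penman–Monteith
formulation for a grass reference crop. The driving data carry no wind or
humidity, so the standard fallbacks are used and exposed as parameters:
2 m wind speed fixed at 2 m s⁻¹, and dew point equal to tmin — a humid
temperate assumption that is reasonable for the UK. Soil heat flux is
zero at the daily step; elevation (default 50 m) sets pressure and
clear-sky radiation. The suite checks the implementation against an
independently coded step-by-step oracle to below 0.01 mm day⁻¹.

## Soil water balance

A deliberately minimal two-layer bucket:

* **Snow.** On days with mean temperature at or below 0 °C precipitation
  accumulates as snow water equivalent; above it, a degree-day model melts
  2.5 mm °C⁻¹ day⁻¹ (capped by the pack) and melt joins infiltration.
  Snow *depth* (the frost-protection criterion is "< 1 cm") is mapped
  from water equivalent at a 10:1 ratio, so < 1 mm SWE counts as bare.
* **Preferential flow.** 15% of infiltration bypasses the working top
  layer (default 40 mm of the profile's available water capacity)
  directly into the lower store.
* **Drainage.** Layer overflow cascades; water above total capacity
  drains the same day.
* **Actual evapotranspiration.** `ETa = ET0 · min(1, W/(r·AWC))` with
  ramp onset `r = 0.25`: extraction is unrestricted while more than a
  quarter of the plant-available store remains, then declines linearly.
  An earlier draft used r = 0.5; composed with the multiplicative
  grain-number drought response below, that made the modelled
  transpiration ratio chronically sub-threshold through ordinary
  early-summer drying and drove the drought index towards total loss in
  dry years — behaviour real wheat on a 177 mm profile does not show. The
  later onset restores index magnitudes to the plausible range and is the
  package's calibration choice; it remains linear, monotone and
  configurable (`et_ramp`).

"At or above field capacity" — the waterlogging criterion — is judged on
the day's *peak* storage (after infiltration and drainage, before the ET
withdrawal), with a 0.999 relative tolerance guarding floating-point
equality: a full, draining profile is waterlogged even though evaporation
ends the day fractionally below capacity. The daily ledger
`precipitation = ΔSWE + ETa + drainage + Δstorage` closes to below
10⁻⁶ mm per day, which the suite asserts over full 300-year runs.

Three named profiles follow the study design: `default180` (180 mm AWC,
used for the event probabilities), `hafren177` (177 mm, the stress-model
soil) and `light127` (127 mm, the light-soil comparison).

## Phenology

Development is thermal-time only: daily `max(0, (tmax+tmin)/2 − base)`
accumulates from the day after a fixed 20 October sowing, with stages at
cumulative targets. Defaults (base 0 °C; 150, 1750 and 800 °C·day for
sowing→emergence, emergence→anthesis, anthesis→maturity) were calibrated
once so the default synthetic site flowers in mid-June and matures in
early August, the typical UK pattern. The emergence→anthesis target is
deliberately larger than field-calibrated thermal sums because the model
has **no vernalisation or photoperiod response**; the inflated target
absorbs, on average, the winter slow-down those mechanisms produce. The
consequence — documented rather than hidden — is that the model
over-responds to warming: uniform warming shortens development everywhere,
whereas a photoperiod-limited crop would resist some of the advance, so
simulated anthesis advances under warming scenarios sit at the high end
of expectation. Warming can only ever advance stages (monotonicity is
property-tested), and a season whose accumulated thermal time never
reaches maturity is flagged as crop failure and excluded with a warning.

## Adverse-event detectors

Seven boolean detectors per crop season (sowing to maturity, indexed by
harvest year), following the published trigger set for winter wheat:

| event | trigger |
|---|---|
| frost, no snow | tmin ≤ −20 °C on ≥1 day with < 1 cm snow |
| late frost | tmin ≤ −2 °C after winter hardiness is lost |
| wet early season | > 60 days at/above field capacity, sowing→anthesis, counting only days with tmean ≥ 3 °C |
| lodging risk | ≥ 2 days (anthesis → maturity−5) with rain > 40 mm, or > 20 mm on soil at capacity the day before |
| grain-filling heat | tmax > 35 °C on ≥ 3 days, anthesis+5 → maturity |
| adverse sowing | < 3 workable days in sowing ± 15 days (top layer 5–90% saturated, rain < 5 mm, previous day ≤ 10 mm) |
| adverse harvest | < 3 workable days in maturity+5 → maturity+25 (top layer < 85%, rain < 0.5 mm, previous day ≤ 5 mm) |

Interpretation choices, each configurable and covered by tests: day counts
are cumulative, not consecutive, except where the trigger itself demands a
spell (the hardiness state machine: lost after ≥ 5 consecutive days with
tmean ≥ 10 °C, regained only after more than 2 consecutive cooler days,
reset at each sowing); saturation percentages refer to the top layer's
available water capacity; the waterlogging criterion uses the whole
profile. Event probability is the fraction of retained years flagged.
Every detector is verified, case by case, against an independently written
naive day-by-day scan on 1,000 randomised synthetic crop years whose
fields are drawn directly from wide distributions (not from the process
models) precisely so that rare triggers fire often.

## The crop stress model

A radiation-use-efficiency summary of a process wheat model, built for
*ratios* of yields rather than absolute yields:

* Leaf area expands linearly in thermal time to `max_lai` (default 6) at
  anthesis and senesces linearly to zero at maturity. Daily biomass is
  `rue · 0.5 · Rs · (1 − exp(−k·LAI))` with extinction k = 0.6 and RUE
  1.5 g DM MJ⁻¹ (intercepted PAR); yield is biomass × harvest index 0.5.
  RUE was calibrated once so the unstressed baseline yields ≈ 8 t ha⁻¹,
  the UK average; the indices below are insensitive to this scaling.
* **Water stress** `f = ETa/ET0` (clipped to [0, 1], 1 when demand is
  zero) multiplies daily assimilation and leaf expansion and accelerates
  senescence (rate × (2 − f)) in rainfed runs; potential runs force
  f = 1. Because stressed leaf area can never exceed unstressed leaf
  area, the yield ordering Yw ≤ Y is structural, and a fully watered
  season reproduces the potential yield exactly.
* **Drought sensitivity.** Over the window 10 days before to 5 days after
  anthesis, each day whose transpiration ratio (proxied by ETa/ET0) falls
  below 0.9 multiplies grain number by ratio/0.9.
* **Heat sensitivity.** In the windows anthesis−10…anthesis and
  anthesis+5…+12, each day above 30 °C sterilises a fraction
  0.05 · (tmax − 30) per °C (clipped to [0, 1]); survivals multiply.

Per retained year the four runs give Y (potential), Yw (water-limited,
tolerant), Ywd (drought-sensitive) and Ywh (heat-sensitive), and the
indices are the fractional losses HSI = 1 − Ywh/Yw, DSI = 1 − Ywd/Yw,
WSI = 1 − Yw/Y (zero where the denominator is zero), each in [0, 1] by
construction. Summaries are the mean and the 95th percentile (the
one-in-twenty-year loss), computed by linear interpolation between order
statistics — `stats::quantile` type 7, fixed and matched against a
sort-based oracle in the tests.

## Ensemble summaries and maps

Each metric is summarised across ensemble members by order statistics
(min, quartiles, median, max; same percentile convention). Site values
interpolate to a map grid by inverse distance weighting with power 2 over
all stations (no search radius), on a local equirectangular projection —
adequate at country extent. IDW is exact at stations and bounded by the
station extrema, both asserted on randomised fields. Grids write as Esri
ASCII rasters; per-year results as CSV; summaries as JSON; and the run
log echoes the configuration and every derived seed.

## Seeding and reproducibility

One master seed drives an experiment. Per-cell seeds derive from it by a
fixed affine-modular rule in the site and scenario indices, so cells are
independent, reproducible in any execution order, and a failed cell
(logged and skipped) never perturbs the others. All seeds stay below
2³¹ − 1. Generation restores the caller's RNG state afterwards.

## What the synthetic test-bed does and does not show

The synthetic sites emulate a temperate maritime regime: seasonal cycles
of temperature and rainfall, first-order wet/dry persistence, skewed
daily amounts, wet-day cloudiness, and east/west rainfall contrasts
(~650 vs ~1050 mm yr⁻¹). Passing tests therefore demonstrate the
machinery — statistical fidelity of the generator, exact perturbation
algebra, mass conservation, detector correctness, index properties and
directional climate responses — under realistic forcing. They do not
validate the absolute event probabilities or stress magnitudes against
observed station records, which would require the real data and
field-calibrated cultivar parameters. Features of real weather the
generator does not represent include interannual variability beyond what
the daily-scale model produces (a known weather-generator limitation),
spell-length changes under climate scenarios, circulation-conditioned
regimes, and sub-daily structure.

## Problem sizes

The shipped tests and the acceptance script use the study's native scale
where that is cheap — 300-year cells with a 50-year spin-up (250 retained
seasons) and a 16-member ensemble — and a 10⁴-year single-site run for
the central-limit fidelity bound; unit tests use 120-year fixtures. A
300-year cell (generation, forcing, two water balances, phenology, seven
detectors, four crop runs) takes a few seconds on one core.

## Known limitations

No vernalisation, photoperiod, nitrogen, pests or diseases; no CO2
physiology (scenario CO2 is metadata only); no runoff routing, water
table or soil temperature; lodging and waterlogging affect the event
probabilities but not simulated yield; cultivar and response-shape
parameters are plausible defaults, not fits to trial data. The drought
index's multiplicative grain-number response compounds quickly once the
transpiration ratio dips below threshold, so its upper tail is sensitive
to the ET ramp onset; that interaction is documented above and the ramp
is exposed as configuration.
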