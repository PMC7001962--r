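Package: wheatrisk
Title: Adverse-Weather Risk Indices for Winter Wheat Under Climate Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic site-scale weather generation (Richardson-type
    first-order Markov chain with gamma wet-day amounts), change-factor
    perturbation for climate-model ensembles, FAO-56 reference
    evapotranspiration, a two-layer soil water balance with snow cover and
    preferential flow, thermal-time winter wheat phenology, seven
    agroclimatic adverse-weather event probabilities (frost without snow,
    late frost, wet early season, lodging, grain-filling heat, adverse
    sowing and harvest conditions), and a radiation-use-efficiency crop
    model yielding heat, drought and water stress indices (HSI, DSI, WSI)
    with ensemble medians, 95th percentiles and inverse-distance-weighted
    maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
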