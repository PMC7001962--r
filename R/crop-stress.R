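#' Crop run configuration
#'
#' Parameters of the radiation-use-efficiency crop model. Yield variants:
#' `"tolerant"` (heat and drought tolerant reference), `"heat_sensitive"`
#' (grain number reduced by heat around anthesis) and `"drought_sensitive"`
#' (grain number reduced by transpiration deficit around flowering). Water
#' mode `"potential"` forces the water stress factor to 1 (irrigated /
#' not water limited); `"rainfed"` takes it from the soil water balance.
#'
#' @param variant yield variant, see above.
#' @param water_mode `"rainfed"` or `"potential"`.
#' @param rue radiation use efficiency (g dry matter per MJ intercepted
#'   PAR).
#' @param max_lai maximum leaf area index reached at anthesis when
#'   unstressed.
#' @param harvest_index_base fraction of final biomass in grain.
#' @param k_ext canopy light extinction coefficient.
#' @param sterility_slope sterile fraction per degC above 30 degC on a heat
#'   day.
#' @param co2_ppm scenario CO2, carried as metadata only (this model version
#'   has no CO2 effect on water-use efficiency).
#' @return object of class `crop_run_config`.
#' @export
crop_run_config <- function(variant = c("tolerant", "heat_sensitive",
                                        "drought_sensitive"),
                            water_mode = c("rainfed", "potential"),
                            rue = 1.5, max_lai = 6, harvest_index_base = 0.5,
                            k_ext = 0.6, sterility_slope = 0.05,
                            co2_ppm = 364) {
  variant <- match.arg(variant)
  water_mode <- match.arg(water_mode)
  stopifnot(rue > 0, harvest_index_base > 0, harvest_index_base < 1,
            max_lai > 0, k_ext > 0, sterility_slope >= 0)
  structure(list(variant = variant, water_mode = water_mode, rue = rue,
                 max_lai = max_lai, harvest_index_base = harvest_index_base,
                 k_ext = k_ext, sterility_slope = sterility_slope,
                 co2_ppm = co2_ppm),
            class = "crop_run_config")
}

#' Daily water stress factor
#'
#' Ratio of actual to reference evapotranspiration, clipped to \[0, 1\];
#' defined as 1 when there is no demand. Scales daily assimilation and leaf
#' expansion, and accelerates senescence, in rainfed runs.
#'
#' @param eta actual evapotranspiration (mm/day).
#' @param et0 reference evapotranspiration (mm/day).
#' @return stress factor in \[0, 1\].
#' @export
water_stress_factor <- function(eta, et0) {
  ifelse(et0 <= 0, 1, pmin(1, pmax(0, eta / et0)))
}

#' Grain-number multiplier from drought around flowering
#'
#' Over the window 10 days before to 5 days after anthesis, each day whose
#' actual:potential transpiration ratio falls below 0.9 contributes a factor
#' `ratio / 0.9`; the multiplier is their product (1 if no day falls below
#' the threshold). Applied to the drought-sensitive variant only.
#'
#' @param ratio daily transpiration-ratio vector for the whole series.
#' @param anthesis day index of anthesis.
#' @param threshold stress threshold on the ratio.
#' @return multiplier in \[0, 1\].
#' @export
drought_grain_factor <- function(ratio, anthesis, threshold = 0.9) {
  i <- (anthesis - 10L):(anthesis + 5L)
  i <- i[i >= 1 & i <= length(ratio)]
  prod(pmin(1, ratio[i] / threshold))
}

#' Grain-number multiplier from heat sterility around anthesis
#'
#' Heat stress acts in two windows: 10 days before anthesis to anthesis
#' (meiosis and fertilisation) and 5 to 12 days after anthesis (early grain
#' filling). On each day with tmax above 30 degC a sterile fraction
#' `slope * (tmax - 30)` (clipped to \[0, 1\]) is induced; surviving
#' fractions combine multiplicatively. Applied to the heat-sensitive
#' variant only.
#'
#' @param tmax daily maxima for the whole series.
#' @param anthesis day index of anthesis.
#' @param slope sterile fraction per degC above the threshold.
#' @param threshold critical temperature (deg C).
#' @return multiplier in \[0, 1\].
#' @export
heat_sterility_factor <- function(tmax, anthesis, slope = 0.05,
                                  threshold = 30) {
  i <- c((anthesis - 10L):anthesis, (anthesis + 5L):(anthesis + 12L))
  i <- i[i >= 1 & i <= length(tmax)]
  sterile <- pmin(1, pmax(0, slope * (tmax[i] - threshold)))
  prod(1 - sterile)
}

# Daily biomass accumulation for one season. LAI expands linearly in thermal
# time to max_lai at anthesis (expansion scaled by the water stress factor)
# and senesces linearly in thermal time to zero at maturity (senescence
# accelerated by stress: rate x (2 - f)). Biomass increment is
# rue * 0.5 * Rs * (1 - exp(-k * LAI)) * f, in g/m2; returned in t/ha.
season_biomass <- function(tt, rs, f, emergence, anthesis, maturity,
                           sowing, cfg, cultivar) {
  lai <- 0
  biomass <- 0
  exp_rate <- cfg$max_lai / cultivar$tt_emergence_to_anthesis
  sen_rate_base <- 1 / cultivar$tt_anthesis_to_maturity
  lai_at_anthesis <- NA_real_
  for (i in emergence:maturity) {
    j <- i - sowing + 1L  # index into season-local tt
    if (i < anthesis) {
      lai <- lai + exp_rate * tt[j] * f[i]
      if (lai > cfg$max_lai) lai <- cfg$max_lai
    } else {
      if (is.na(lai_at_anthesis)) lai_at_anthesis <- lai
      lai <- lai - lai_at_anthesis * sen_rate_base * tt[j] * (2 - f[i])
      if (lai < 0) lai <- 0
    }
    par_int <- 0.5 * rs[i] * (1 - exp(-cfg$k_ext * lai))
    biomass <- biomass + cfg$rue * par_int * f[i]
  }
  biomass * 0.01  # g/m2 -> t/ha
}

#' Simulate one season's grain yield
#'
#' Radiation-use-efficiency model: daily intercepted PAR drives biomass,
#' leaf area expands to `max_lai` by anthesis and senesces to zero by
#' maturity (both thermal-time paced and modulated by the water stress
#' factor in rainfed mode), and yield is biomass times harvest index times
#' the variant's grain-number multiplier. Deterministic given its inputs.
#'
#' @param series weather_series with `radiation` (see [compute_forcing()]).
#' @param soil water-balance trajectory aligned with `series` (ignored in
#'   potential mode).
#' @param pheno one-season [predict_stages()] result or one row of
#'   [season_phenology()].
#' @param cultivar [cultivar_params()].
#' @param cfg [crop_run_config()].
#' @return yield (t/ha).
#' @export
simulate_crop <- function(series, soil, pheno, cultivar = cultivar_params(),
                          cfg = crop_run_config()) {
  sow <- pheno$sowing; anth <- pheno$anthesis; mat <- pheno$maturity
  if (is.na(mat)) stop("crop failure: maturity not reached")
  if (cfg$water_mode == "potential") {
    f <- rep(1, nrow(series))
  } else {
    f <- water_stress_factor(soil$eta, series$et0)
  }
  tt <- daily_thermal_time(series$tmax[sow:mat], series$tmin[sow:mat],
                           cultivar$base_temperature)
  biomass <- season_biomass(tt, series$radiation, f, pheno$emergence, anth,
                            mat, sow, cfg, cultivar)
  mult <- switch(cfg$variant,
    tolerant = 1,
    heat_sensitive = heat_sterility_factor(series$tmax, anth,
                                           cfg$sterility_slope),
    drought_sensitive = drought_grain_factor(f, anth))
  biomass * cfg$harvest_index_base * mult
}

#' Simulate the four-yield set for every season
#'
#' Per harvest year: `Y` potential yield (not water limited), `Yw`
#' water-limited yield of the tolerant reference, `Ywd` water-limited yield
#' of the drought-sensitive variant, `Ywh` water- and heat-limited yield of
#' the heat-sensitive variant. By construction
#' `0 <= Ywh <= Yw <= Y` and `0 <= Ywd <= Yw`.
#'
#' @param series weather_series with `radiation` and `et0`.
#' @param soil rainfed water-balance trajectory aligned with `series`.
#' @param pheno season table from [season_phenology()].
#' @param cultivar [cultivar_params()].
#' @param cfg [crop_run_config()] (its `variant`/`water_mode` are
#'   overridden per run).
#' @return data.frame: `harvest_year`, `Y`, `Yw`, `Ywd`, `Ywh`.
#' @export
simulate_yield_set <- function(series, soil, pheno,
                               cultivar = cultivar_params(),
                               cfg = crop_run_config()) {
  n <- nrow(pheno)
  Y <- Yw <- Ywd <- Ywh <- numeric(n)
  cfg_pot <- cfg; cfg_pot$water_mode <- "potential"; cfg_pot$variant <- "tolerant"
  cfg_w <- cfg; cfg_w$water_mode <- "rainfed"; cfg_w$variant <- "tolerant"
  f <- water_stress_factor(soil$eta, series$et0)
  for (k in seq_len(n)) {
    ph <- pheno[k, ]
    Y[k] <- simulate_crop(series, soil, ph, cultivar, cfg_pot)
    Yw[k] <- simulate_crop(series, soil, ph, cultivar, cfg_w)
    Ywd[k] <- Yw[k] * drought_grain_factor(f, ph$anthesis)
    Ywh[k] <- Yw[k] * heat_sterility_factor(series$tmax, ph$anthesis,
                                            cfg$sterility_slope)
  }
  data.frame(harvest_year = pheno$harvest_year, Y = Y, Yw = Yw, Ywd = Ywd,
             Ywh = Ywh)
}

#' Heat, drought and water stress indices
#'
#' Per-year fractional yield losses: `HSI = 1 - Ywh/Yw`,
#' `DSI = 1 - Ywd/Yw`, `WSI = 1 - Yw/Y` (0 where the denominator is 0),
#' with means and 95th percentiles (one-in-twenty-year loss) across years.
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param yields data.frame from [simulate_yield_set()].
#' @return list of class `stress_indices`: `per_year` (data.frame with
#'   HSI/DSI/WSI) and `summary` (mean and p95 per index).
#' @export
compute_stress_indices <- function(yields) {
  loss <- function(num, den)
    ifelse(den > 0, pmin(1, pmax(0, 1 - num / den)), 0)
  per_year <- data.frame(
    harvest_year = yields$harvest_year,
    HSI = loss(yields$Ywh, yields$Yw),
    DSI = loss(yields$Ywd, yields$Yw),
    WSI = loss(yields$Yw, yields$Y))
  q95 <- function(x) unname(stats::quantile(x, 0.95, type = 7))
  summary <- data.frame(
    index = c("HSI", "DSI", "WSI"),
    mean = c(mean(per_year$HSI), mean(per_year$DSI), mean(per_year$WSI)),
    p95 = c(q95(per_year$HSI), q95(per_year$DSI), q95(per_year$WSI)),
    row.names = NULL)
  structure(list(per_year = per_year, summary = summary),
            class = "stress_indices")
}

#' @export
print.stress_indices <- function(x, ...) {
  cat(sprintf("<stress_indices> %d years\n", nrow(x$per_year)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s: mean %.3f, 95th percentile %.3f\n",
                s$index[i], s$mean[i], s$p95[i]))
  invisible(x)
}
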