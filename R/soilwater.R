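#' Soil profile definition
#'
#' Two-layer bucket: a thin working top layer (seedbed / harvest
#' trafficability horizon) and the remaining root-zone store. The standard
#' profiles are `"default180"` (180 mm available water capacity, used for
#' the event probabilities), `"hafren177"` (177 mm, stress indices) and
#' `"light127"` (127 mm light soil).
#'
#' @param awc_total total available water capacity (mm), or one of the
#'   preset names above.
#' @param top_layer_awc capacity of the top layer (mm, default 40).
#' @param preferential_flow_fraction fraction of infiltration that bypasses
#'   the top layer directly into the lower store.
#' @param name label.
#' @return object of class `soil_profile`.
#' @export
soil_profile <- function(awc_total, top_layer_awc = 40,
                         preferential_flow_fraction = 0.15, name = NULL) {
  if (is.character(awc_total)) {
    presets <- c(default180 = 180, hafren177 = 177, light127 = 127)
    if (!awc_total %in% names(presets))
      stop("unknown soil profile '", awc_total, "'; presets: ",
           paste(names(presets), collapse = ", "))
    name <- awc_total
    awc_total <- unname(presets[awc_total])
  }
  stopifnot(awc_total > 0, top_layer_awc > 0, top_layer_awc < awc_total,
            preferential_flow_fraction >= 0, preferential_flow_fraction <= 1)
  structure(list(awc_total = awc_total, top_layer_awc = top_layer_awc,
                 lower_awc = awc_total - top_layer_awc,
                 preferential_flow_fraction = preferential_flow_fraction,
                 name = if (is.null(name)) sprintf("awc%d", round(awc_total))
                        else name),
            class = "soil_profile")
}

#' @export
print.soil_profile <- function(x, ...) {
  cat(sprintf("<soil_profile> %s: AWC %g mm (top %g mm), preferential flow %.0f%%\n",
              x$name, x$awc_total, x$top_layer_awc,
              100 * x$preferential_flow_fraction))
  invisible(x)
}

#' Soil state
#'
#' @param moisture_top,moisture_lower plant-available water in each layer
#'   (mm).
#' @param swe snow water equivalent (mm).
#' @return list of class `soil_state`; diagnostic fields (`infiltration`,
#'   `eta`, `drainage`) are filled by the step functions.
#' @export
soil_state <- function(moisture_top, moisture_lower, swe = 0) {
  stopifnot(moisture_top >= 0, moisture_lower >= 0, swe >= 0)
  structure(list(moisture_top = moisture_top, moisture_lower = moisture_lower,
                 swe = swe, infiltration = 0, eta = 0, drainage = 0),
            class = "soil_state")
}

#' Daily snow accumulation / degree-day melt step
#'
#' Below the snow temperature threshold (on daily mean temperature) all
#' precipitation accumulates as snow water equivalent and nothing
#' infiltrates; above it, snow melts at `melt_factor` mm per degC per day
#' (capped by the pack) and melt plus rain become infiltration.
#'
#' @param state `soil_state`.
#' @param tmean daily mean temperature (deg C).
#' @param precip daily precipitation (mm).
#' @param snow_temp threshold (deg C, default 0).
#' @param melt_factor degree-day melt factor (mm/degC/day, default 2.5).
#' @return updated state with `$infiltration` set (mm available to the soil).
#' @export
step_snow <- function(state, tmean, precip, snow_temp = 0,
                      melt_factor = 2.5) {
  if (tmean <= snow_temp) {
    state$swe <- state$swe + precip
    state$infiltration <- 0
  } else {
    melt <- min(state$swe, melt_factor * (tmean - snow_temp))
    state$swe <- state$swe - melt
    state$infiltration <- precip + melt
  }
  state
}

#' Daily water-balance step
#'
#' A fixed fraction of infiltration bypasses the top layer (preferential
#' flow); the rest tops up the top layer, whose overflow cascades to the
#' lower store, whose overflow drains. Actual evapotranspiration is the
#' reference demand scaled by a linear moisture ramp,
#' `ETa = ET0 * min(1, W / (et_ramp * AWC))` — unrestricted while stored
#' water exceeds `et_ramp` (default 25%) of capacity, declining linearly to
#' zero with the store below it — withdrawn from the top layer first. The
#' daily budget `infiltration = ETa + drainage + dStorage` closes to
#' machine precision.
#'
#' @param state `soil_state` (after [step_snow()]).
#' @param infiltration water reaching the soil surface (mm).
#' @param et0 reference evapotranspiration demand (mm).
#' @param profile [soil_profile()].
#' @param fc_tolerance relative storage counting as at field capacity.
#' @param et_ramp fraction of capacity below which ET is linearly reduced.
#' @return updated state with `$eta`, `$drainage` and `$at_or_above_fc`
#'   diagnostics (field capacity judged on the day's peak storage, before
#'   the ET withdrawal).
#' @export
step_water_balance <- function(state, infiltration, et0, profile,
                               fc_tolerance = 0.999, et_ramp = 0.25) {
  top <- state$moisture_top + (1 - profile$preferential_flow_fraction) *
    infiltration
  lower <- state$moisture_lower + profile$preferential_flow_fraction *
    infiltration
  spill <- max(0, top - profile$top_layer_awc)
  top <- top - spill
  lower <- lower + spill
  drainage <- max(0, lower - profile$lower_awc)
  lower <- lower - drainage

  total <- top + lower
  state$at_or_above_fc <- total >= fc_tolerance * profile$awc_total
  eta <- et0 * min(1, total / (et_ramp * profile$awc_total))
  eta <- min(eta, total)
  from_top <- min(eta, top)
  top <- top - from_top
  lower <- lower - (eta - from_top)

  state$moisture_top <- top
  state$moisture_lower <- lower
  state$eta <- eta
  state$drainage <- drainage
  state
}

#' Run the daily soil water balance over a weather series
#'
#' Applies [step_snow()] then [step_water_balance()] every day (inlined for
#' speed; equivalence with the exported step functions is part of the test
#' suite). The first `spin-up` years of a run equilibrate the store and are
#' discarded by consumers.
#'
#' @param series weather_series with an `et0` column (see
#'   [compute_forcing()]), or `et0` supplied separately.
#' @param profile [soil_profile()].
#' @param et0 optional per-day reference evapotranspiration (mm).
#' @param init initial relative filling: `"half"`, `"full"` or `"empty"`.
#' @param snow_temp,melt_factor snow parameters, see [step_snow()].
#' @param fc_tolerance relative moisture at or above which the profile
#'   counts as at field capacity (guards floating-point equality).
#' @param et_ramp fraction of capacity below which ET is linearly reduced.
#' @return data.frame trajectory: `year`, `doy`, `swe`, `moisture_top`,
#'   `moisture_total`, `rel_sat_top`, `at_fc`, `eta`, `drainage`,
#'   `infiltration`.
#' @export
run_water_balance <- function(series, profile, et0 = NULL,
                              init = c("half", "full", "empty"),
                              snow_temp = 0, melt_factor = 2.5,
                              fc_tolerance = 0.999, et_ramp = 0.25) {
  init <- match.arg(init)
  if (is.null(et0)) {
    if (!("et0" %in% names(series)))
      stop("series has no et0 column; run compute_forcing() or pass et0")
    et0 <- series$et0
  }
  n <- nrow(series)
  stopifnot(length(et0) == n)
  tmean <- (series$tmax + series$tmin) / 2
  precip <- series$precip
  pf <- profile$preferential_flow_fraction
  top_cap <- profile$top_layer_awc
  low_cap <- profile$lower_awc
  awc <- profile$awc_total

  fill <- switch(init, half = 0.5, full = 1, empty = 0)
  top <- fill * top_cap
  lower <- fill * low_cap
  swe <- 0

  o_swe <- o_top <- o_tot <- o_eta <- o_drn <- o_inf <- numeric(n)
  o_fc <- logical(n)
  for (i in seq_len(n)) {
    # snow
    if (tmean[i] <= snow_temp) {
      swe <- swe + precip[i]
      inf <- 0
    } else {
      melt <- min(swe, melt_factor * (tmean[i] - snow_temp))
      swe <- swe - melt
      inf <- precip[i] + melt
    }
    # infiltration with preferential bypass, cascade drainage
    top <- top + (1 - pf) * inf
    lower <- lower + pf * inf
    if (top > top_cap) { lower <- lower + (top - top_cap); top <- top_cap }
    drn <- if (lower > low_cap) lower - low_cap else 0
    lower <- lower - drn
    # at-field-capacity is judged on the day's peak storage (after
    # infiltration and drainage, before ET withdrawal): a full, draining
    # profile is waterlogged even though evaporation ends the day below FC
    total <- top + lower
    o_fc[i] <- total >= fc_tolerance * awc
    # moisture-limited evapotranspiration, top layer first
    eta <- et0[i] * min(1, total / (et_ramp * awc))
    if (eta > total) eta <- total
    if (eta <= top) top <- top - eta else { lower <- lower - (eta - top); top <- 0 }

    o_swe[i] <- swe; o_top[i] <- top; o_tot[i] <- top + lower
    o_eta[i] <- eta; o_drn[i] <- drn; o_inf[i] <- inf
  }
  data.frame(year = series$year, doy = series$doy, swe = o_swe,
             moisture_top = o_top, moisture_total = o_tot,
             rel_sat_top = o_top / top_cap,
             at_fc = o_fc,
             eta = o_eta, drainage = o_drn, infiltration = o_inf)
}
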