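#' Winter wheat cultivar parameters
#'
#' Thermal-time targets (degC day above `base_temperature`) for the three
#' development phases sowing-emergence, emergence-anthesis and
#' anthesis-maturity. The defaults describe a medium-ripening cultivar
#' calibrated so that a 20 October sowing under the UK-like synthetic
#' baseline climate reaches anthesis in mid June and maturity in early
#' August (see the methods vignette for the calibration).
#'
#' @param base_temperature base temperature (deg C).
#' @param tt_sowing_to_emergence,tt_emergence_to_anthesis,tt_anthesis_to_maturity
#'   phase targets (degC day, > 0).
#' @param label cultivar label.
#' @return object of class `cultivar_params`.
#' @export
cultivar_params <- function(base_temperature = 0,
                            tt_sowing_to_emergence = 150,
                            tt_emergence_to_anthesis = 1750,
                            tt_anthesis_to_maturity = 800,
                            label = "medium-ripening") {
  stopifnot(tt_sowing_to_emergence > 0, tt_emergence_to_anthesis > 0,
            tt_anthesis_to_maturity > 0)
  structure(list(base_temperature = base_temperature,
                 tt_sowing_to_emergence = tt_sowing_to_emergence,
                 tt_emergence_to_anthesis = tt_emergence_to_anthesis,
                 tt_anthesis_to_maturity = tt_anthesis_to_maturity,
                 label = label),
            class = "cultivar_params")
}

#' Daily thermal time
#'
#' `max(0, (tmax + tmin)/2 - base)`, degC day.
#'
#' @param tmax,tmin daily extremes (deg C), vectorised.
#' @param base base temperature (deg C).
#' @return thermal time (degC day).
#' @export
daily_thermal_time <- function(tmax, tmin, base = 0) {
  stopifnot(all(tmax >= tmin))
  pmax(0, (tmax + tmin) / 2 - base)
}

#' Predict development dates for one crop season
#'
#' Accumulates thermal time from the day after sowing (the sowing day
#' itself contributes no development, so with constant thermal time `r` a
#' target `T` is met exactly `T/r` days after sowing); each stage is
#' reached on the first day the cumulative sum meets its target. Temperature rates
#' (degC day per day) are reported for sowing-anthesis and
#' anthesis-maturity. If maturity is not reached within the available
#' window the season is flagged as failed (`maturity = NA`).
#'
#' @param series weather_series (full multi-year series is fine).
#' @param sowing_index row index of the sowing day in `series`.
#' @param cultivar [cultivar_params()].
#' @param max_season_days scan horizon after sowing (default 365).
#' @return list of class `pheno_dates`: row indices `sowing`, `emergence`,
#'   `anthesis`, `maturity` (absolute in `series`), their `doy` values,
#'   `harvest_year`, the two temperature rates and `failed`.
#' @export
predict_stages <- function(series, sowing_index, cultivar = cultivar_params(),
                           max_season_days = 365) {
  n <- nrow(series)
  stopifnot(sowing_index >= 1, sowing_index <= n)
  last <- min(n, sowing_index + max_season_days)
  idx <- (sowing_index + 1L):last
  tt <- daily_thermal_time(series$tmax[idx], series$tmin[idx],
                           cultivar$base_temperature)
  ctt <- cumsum(tt)
  t_em <- cultivar$tt_sowing_to_emergence
  t_an <- t_em + cultivar$tt_emergence_to_anthesis
  t_mat <- t_an + cultivar$tt_anthesis_to_maturity
  first_at <- function(target) {
    i <- match(TRUE, ctt >= target)
    if (is.na(i)) NA_integer_ else idx[i]
  }
  emergence <- first_at(t_em)
  anthesis <- first_at(t_an)
  maturity <- first_at(t_mat)
  failed <- is.na(maturity)
  rate <- function(from, to, tt_total) {
    if (is.na(to) || to <= from) return(NA_real_)
    tt_total / (to - from)
  }
  structure(list(
    sowing = sowing_index, emergence = emergence, anthesis = anthesis,
    maturity = maturity,
    sowing_doy = series$doy[sowing_index],
    emergence_doy = if (is.na(emergence)) NA_integer_ else series$doy[emergence],
    anthesis_doy = if (is.na(anthesis)) NA_integer_ else series$doy[anthesis],
    maturity_doy = if (is.na(maturity)) NA_integer_ else series$doy[maturity],
    harvest_year = if (is.na(maturity)) NA_integer_ else series$year[maturity],
    temperature_rate_sowing_anthesis = rate(sowing_index, anthesis, t_an),
    temperature_rate_anthesis_maturity =
      if (is.na(anthesis)) NA_real_
      else rate(anthesis, maturity, cultivar$tt_anthesis_to_maturity),
    failed = failed), class = "pheno_dates")
}

#' @export
print.pheno_dates <- function(x, ...) {
  if (x$failed) {
    cat("<pheno_dates> crop failure: maturity not reached\n")
  } else {
    cat(sprintf(
      "<pheno_dates> sowing doy %d -> emergence %d -> anthesis %d -> maturity %d (harvest year %d)\n",
      x$sowing_doy, x$emergence_doy, x$anthesis_doy, x$maturity_doy,
      x$harvest_year))
  }
  invisible(x)
}

#' Phenology for every season of a multi-year series
#'
#' Sows on `sowing_doy` of each year that leaves room for a full season plus
#' the post-maturity harvest window, and predicts the stage dates. Failed
#' seasons (maturity not reached) are dropped with a warning.
#'
#' @param series weather_series.
#' @param sowing_doy sowing day of year (default 293 = 20 October).
#' @param cultivar [cultivar_params()].
#' @param trailing_days days needed after maturity (harvest window; rows
#'   whose season cannot provide them are not sown).
#' @return data.frame, one row per harvest year: indices and doys of the
#'   four stages, temperature rates.
#' @export
season_phenology <- function(series, sowing_doy = SOWING_DOY_DEFAULT,
                             cultivar = cultivar_params(),
                             trailing_days = 25) {
  years <- unique(series$year)
  first_year <- min(years)
  out <- list()
  for (y in years) {
    sow_idx <- (y - first_year) * DAYS_PER_YEAR + sowing_doy
    if (sow_idx + 365 + trailing_days > nrow(series)) break
    ph <- predict_stages(series, sow_idx, cultivar)
    if (ph$failed) {
      warning("crop failure: maturity not reached for sowing year ", y,
              "; season excluded")
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      sowing_year = y, harvest_year = ph$harvest_year,
      sowing = ph$sowing, emergence = ph$emergence, anthesis = ph$anthesis,
      maturity = ph$maturity, sowing_doy = ph$sowing_doy,
      emergence_doy = ph$emergence_doy, anthesis_doy = ph$anthesis_doy,
      maturity_doy = ph$maturity_doy,
      temperature_rate_sowing_anthesis = ph$temperature_rate_sowing_anthesis,
      temperature_rate_anthesis_maturity = ph$temperature_rate_anthesis_maturity)
  }
  if (!length(out)) stop("no complete crop season in series")
  do.call(rbind, out)
}
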