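#' Astronomical daylength
#'
#' Hours between sunrise and sunset from solar declination and the sunset
#' hour angle.
#'
#' @param latitude degrees (|latitude| < 66.5).
#' @param doy day of year (365-day calendar), vectorised.
#' @return daylength in hours.
#' @export
daylength <- function(latitude, doy) {
  extraterrestrial_radiation(latitude, doy)$N
}

#' Extraterrestrial radiation and daylength
#'
#' Standard solar-geometry computation: inverse relative Earth-Sun distance,
#' solar declination, sunset hour angle, then top-of-atmosphere radiation
#' `Ra` (MJ m-2 day-1) and daylength `N` (hours). Solar constant
#' 0.0820 MJ m-2 min-1.
#'
#' @param latitude degrees; polar latitudes (>= 66.5 in absolute value) are
#'   an error as the sunset hour angle degenerates.
#' @param doy day of year, vectorised.
#' @return data.frame with columns `Ra` and `N`.
#' @export
extraterrestrial_radiation <- function(latitude, doy) {
  if (abs(latitude) >= 66.5)
    stop("polar latitude: extraterrestrial radiation undefined year-round")
  stopifnot(all(doy >= 1), all(doy <= 366))
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(pmin(pmax(-tan(phi) * tan(delta), -1), 1))
  Gsc <- 0.0820
  Ra <- 24 * 60 / pi * Gsc * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
  data.frame(Ra = pmax(Ra, 0), N = 24 / pi * ws)
}

#' Convert sunshine hours to solar radiation (Angstrom-Prescott)
#'
#' `Rs = (a + b * n/N) * Ra`. Defaults a = 0.25, b = 0.50 are the usual
#' values where no locally fitted coefficients exist.
#'
#' @param sun_hours bright sunshine hours `n`.
#' @param Ra extraterrestrial radiation (MJ m-2 day-1).
#' @param N daylength (hours).
#' @param a,b regression coefficients (> 0).
#' @return solar radiation Rs (MJ m-2 day-1).
#' @export
sunshine_to_radiation <- function(sun_hours, Ra, N, a = 0.25, b = 0.50) {
  stopifnot(a > 0, b > 0)
  if (any(sun_hours > N + 1e-9)) {
    warning("sun_hours exceeds daylength; clamping")
    sun_hours <- pmin(sun_hours, N)
  }
  sun_hours <- pmax(sun_hours, 0)
  (a + b * sun_hours / pmax(N, 1e-9)) * Ra
}

#' Daily FAO-56 Penman-Monteith reference evapotranspiration
#'
#' Full daily formulation for a grass reference surface. Wind speed and
#' humidity are rarely in the driving data, so the standard fallbacks are
#' used: 2 m wind fixed at `wind_speed` (default 2 m/s) and dew point equal
#' to tmin (humid temperate assumption), giving the actual vapour pressure.
#' Soil heat flux is zero at the daily step. Results are floored at zero.
#'
#' @param tmax,tmin daily extremes (deg C), vectorised.
#' @param rs solar radiation (MJ m-2 day-1).
#' @param latitude degrees.
#' @param doy day of year.
#' @param elevation site elevation (m), used for pressure and clear-sky
#'   radiation.
#' @param wind_speed 2 m wind speed (m/s).
#' @return data.frame echoing inputs plus `et0` (mm/day).
#' @export
penman_monteith_et0 <- function(tmax, tmin, rs, latitude, doy,
                                elevation = 50, wind_speed = 2) {
  stopifnot(all(tmax >= tmin))
  tmean <- (tmax + tmin) / 2
  # psychrometrics
  P <- 101.3 * ((293 - 0.0065 * elevation) / 293)^5.26
  gamma <- 0.000665 * P
  es_t <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
  es <- (es_t(tmax) + es_t(tmin)) / 2
  ea <- es_t(tmin)                       # dew point ~ tmin
  delta <- 4098 * es_t(tmean) / (tmean + 237.3)^2
  # radiation balance
  Ra <- extraterrestrial_radiation(latitude, doy)$Ra
  Rso <- (0.75 + 2e-5 * elevation) * Ra
  rel <- ifelse(Rso > 0, pmin(pmax(rs / Rso, 0.25), 1), 0.25)
  sigma <- 4.903e-9
  tK4 <- ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2
  Rnl <- sigma * tK4 * (0.34 - 0.14 * sqrt(pmax(ea, 0))) * (1.35 * rel - 0.35)
  Rn <- 0.77 * rs - Rnl                  # albedo 0.23, G = 0 daily
  u2 <- wind_speed
  et0 <- (0.408 * delta * Rn + gamma * 900 / (tmean + 273) * u2 * (es - ea)) /
    (delta + gamma * (1 + 0.34 * u2))
  data.frame(doy = doy, tmax = tmax, tmin = tmin, rs = rs, u2 = u2, ea = ea,
             et0 = pmax(et0, 0))
}

#' Add radiation and reference evapotranspiration to a weather series
#'
#' Fills the `radiation` column from sunshine hours where absent and
#' appends `et0` (mm/day), using the site's latitude and elevation.
#'
#' @param series weather_series.
#' @param a,b Angstrom coefficients for [sunshine_to_radiation()].
#' @param wind_speed 2 m wind speed (m/s).
#' @return weather_series with `radiation` and `et0` columns.
#' @export
compute_forcing <- function(series, a = 0.25, b = 0.50, wind_speed = 2) {
  site <- series_site(series)
  sol <- extraterrestrial_radiation(site$latitude, series$doy)
  if (!("radiation" %in% names(series)) || anyNA(series$radiation)) {
    series$radiation <- sunshine_to_radiation(series$sun_hours, sol$Ra,
                                              sol$N, a, b)
  }
  series$et0 <- penman_monteith_et0(series$tmax, series$tmin,
                                    series$radiation, site$latitude,
                                    series$doy, site$elevation,
                                    wind_speed)$et0
  series
}
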