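# Independent naive re-implementations used as oracles. These are written
# as literal day-by-day scans of the published trigger definitions, with no
# code shared with the package implementations.

naive_frost_no_snow <- function(yr) {
  for (i in yr$sowing:yr$maturity) {
    if (yr$tmin[i] <= -20 && yr$swe[i] < 1) return(TRUE)
  }
  FALSE
}

naive_late_frost <- function(yr) {
  hardy <- TRUE
  i <- yr$sowing
  while (i <= yr$maturity) {
    if (hardy) {
      # scan for a warm spell of at least 5 consecutive days
      run <- 0
      while (i <= yr$maturity) {
        if (yr$tmean[i] >= 10) {
          run <- run + 1
          if (run >= 5) { hardy <- FALSE; break }
        } else run <- 0
        i <- i + 1
      }
      if (hardy) return(FALSE)  # reached season end still hardy
      if (yr$tmin[i] <= -2) return(TRUE)
      i <- i + 1
    } else {
      # vulnerable: frost fires unless 3 cool days in a row re-harden first
      cool <- 0
      while (i <= yr$maturity) {
        if (yr$tmean[i] < 10) {
          cool <- cool + 1
        } else cool <- 0
        if (cool >= 3) { hardy <- TRUE; i <- i + 1; break }
        if (yr$tmin[i] <= -2) return(TRUE)
        i <- i + 1
      }
    }
  }
  FALSE
}

naive_wet_early_season <- function(yr) {
  count <- 0
  i <- yr$sowing
  while (i < yr$anthesis) {
    if (yr$at_fc[i] && yr$tmean[i] >= 3) count <- count + 1
    i <- i + 1
  }
  count > 60
}

naive_lodging <- function(yr) {
  count <- 0
  for (i in yr$anthesis:(yr$maturity - 5)) {
    if (i > yr$maturity - 5) break
    heavy <- yr$precip[i] > 40
    moderate <- yr$precip[i] > 20 && i > 1 && yr$at_fc[i - 1]
    if (heavy || moderate) count <- count + 1
  }
  if (yr$maturity - 5 < yr$anthesis) return(FALSE)
  count >= 2
}

naive_grainfill_heat <- function(yr) {
  count <- 0
  i <- yr$anthesis + 5
  while (i <= yr$maturity) {
    if (yr$tmax[i] > 35) count <- count + 1
    i <- i + 1
  }
  count >= 3
}

naive_adverse_sowing <- function(yr) {
  workable <- 0
  for (i in (yr$sowing - 15):(yr$sowing + 15)) {
    if (i < 2) next
    sat_ok <- yr$rel_sat_top[i] < 0.90 && yr$rel_sat_top[i] > 0.05
    rain_ok <- yr$precip[i] < 5 && yr$precip[i - 1] <= 10
    if (sat_ok && rain_ok) workable <- workable + 1
  }
  workable < 3
}

naive_adverse_harvest <- function(yr) {
  workable <- 0
  for (i in (yr$maturity + 5):(yr$maturity + 25)) {
    if (yr$rel_sat_top[i] < 0.85 && yr$precip[i] < 0.5 &&
        yr$precip[i - 1] <= 5) workable <- workable + 1
  }
  workable < 3
}

# package-side detector calls on the same random crop-year slice
package_detectors <- function(yr) {
  c(frost_no_snow = detect_frost_no_snow(yr$tmin, yr$swe, yr$sowing,
                                         yr$maturity),
    late_frost = detect_late_frost(yr$tmean, yr$tmin, yr$sowing,
                                   yr$maturity),
    wet_early_season = detect_wet_early_season(yr$at_fc, yr$tmean,
                                               yr$sowing, yr$anthesis),
    lodging_risk = detect_lodging_risk(yr$precip, yr$at_fc, yr$anthesis,
                                       yr$maturity),
    grainfill_heat = detect_grainfill_heat(yr$tmax, yr$anthesis,
                                           yr$maturity),
    adverse_sowing = detect_adverse_sowing(yr$rel_sat_top, yr$precip,
                                           yr$sowing),
    adverse_harvest = detect_adverse_harvest(yr$rel_sat_top, yr$precip,
                                             yr$maturity))
}

naive_detectors <- function(yr) {
  c(frost_no_snow = naive_frost_no_snow(yr),
    late_frost = naive_late_frost(yr),
    wet_early_season = naive_wet_early_season(yr),
    lodging_risk = naive_lodging(yr),
    grainfill_heat = naive_grainfill_heat(yr),
    adverse_sowing = naive_adverse_sowing(yr),
    adverse_harvest = naive_adverse_harvest(yr))
}

# Step-by-step daily grass-reference Penman-Monteith, coded independently
# (scalar arithmetic, Murray's saturation-vapour formulation written out).
fao56_oracle <- function(tmax, tmin, rs, lat_deg, doy, elev = 50, u2 = 2) {
  tmean <- (tmax + tmin) / 2
  svp <- function(t) 0.6108 * exp((17.27 * t) / (237.3 + t))
  delta <- (4098 * svp(tmean)) / (237.3 + tmean)^2
  pressure <- 101.3 * ((293 - 0.0065 * elev) / 293)^5.26
  psy <- 0.000665 * pressure
  es <- (svp(tmax) + svp(tmin)) / 2
  ea <- svp(tmin)
  phi <- pi / 180 * lat_deg
  dr <- 1 + 0.033 * cos(2 * pi / 365 * doy)
  decl <- 0.409 * sin(2 * pi / 365 * doy - 1.39)
  x <- -tan(phi) * tan(decl)
  x <- min(1, max(-1, x))
  ws <- acos(x)
  ra <- (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
  rso <- (0.75 + 2e-5 * elev) * ra
  ratio <- if (rso > 0) rs / rso else 0.25
  ratio <- min(1, max(0.25, ratio))
  rnl <- 4.903e-9 * (((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2) *
    (0.34 - 0.14 * sqrt(max(ea, 0))) * (1.35 * ratio - 0.35)
  rns <- (1 - 0.23) * rs
  rn <- rns - rnl
  num <- 0.408 * delta * rn + psy * (900 / (tmean + 273)) * u2 * (es - ea)
  den <- delta + psy * (1 + 0.34 * u2)
  max(0, num / den)
}

# sort-based percentile oracle (linear interpolation between order stats,
# matching the documented convention)
percentile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}
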