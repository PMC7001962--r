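# Seven per-season adverse-weather event detectors. Each takes plain daily
# vectors covering the whole simulated series plus stage indices, so they can
# be driven equally by the pipeline and by randomised property tests. Counting
# thresholds follow the published trigger table: counts are cumulative (not
# consecutive) except where the trigger itself demands a consecutive spell.

#' Severe frost with no protective snow cover
#'
#' True if any day in \[from, to\] has tmin <= -20 degC while snow depth is
#' below 1 cm. The balance model carries snow water equivalent; depth is
#' mapped at a 10:1 depth:water ratio, so < 1 cm of snow corresponds to
#' swe < 1 mm.
#'
#' @param tmin,swe daily vectors for the whole series.
#' @param from,to index window (typically sowing to maturity).
#' @param tmin_threshold,swe_threshold trigger thresholds.
#' @return logical.
#' @export
detect_frost_no_snow <- function(tmin, swe, from, to,
                                 tmin_threshold = -20, swe_threshold = 1) {
  i <- from:to
  any(tmin[i] <= tmin_threshold & swe[i] < swe_threshold)
}

#' Late frost after loss of winter hardiness
#'
#' Hardiness is lost once mean air temperature has been at or above 10 degC
#' for at least 5 consecutive days, and is only regained after the mean
#' drops below 10 degC for more than 2 days in a row. The event fires if
#' tmin <= -2 degC on any day while hardiness is lost. The state machine
#' starts hardy at `from` (each season afresh).
#'
#' @param tmean,tmin daily vectors.
#' @param from,to index window (sowing to maturity).
#' @param warm_threshold,warm_days warm-spell definition (>= 10 degC,
#'   >= 5 days).
#' @param cool_days consecutive cool days (> 2) needed to re-harden.
#' @param frost_threshold damaging minimum (<= -2 degC).
#' @return logical.
#' @export
detect_late_frost <- function(tmean, tmin, from, to, warm_threshold = 10,
                              warm_days = 5, cool_days = 3,
                              frost_threshold = -2) {
  hardy <- TRUE
  warm_run <- 0L
  cool_run <- 0L
  for (i in from:to) {
    if (tmean[i] >= warm_threshold) {
      warm_run <- warm_run + 1L
      cool_run <- 0L
      if (hardy && warm_run >= warm_days) hardy <- FALSE
    } else {
      cool_run <- cool_run + 1L
      warm_run <- 0L
      if (!hardy && cool_run >= cool_days) hardy <- TRUE
    }
    if (!hardy && tmin[i] <= frost_threshold) return(TRUE)
  }
  FALSE
}

#' Extremely wet early season (waterlogging risk)
#'
#' Counts days from sowing up to (but excluding) anthesis with the soil at
#' or above field capacity; days with mean temperature below 3 degC do not
#' count. True if the (cumulative) count exceeds 60 days.
#'
#' @param at_fc logical daily at-field-capacity flags.
#' @param tmean daily mean temperature.
#' @param sowing,anthesis day indices.
#' @param min_days threshold (event if count > min_days).
#' @param tmean_min minimum counting temperature.
#' @return logical.
#' @export
detect_wet_early_season <- function(at_fc, tmean, sowing, anthesis,
                                    min_days = 60, tmean_min = 3) {
  if (anthesis <= sowing) return(FALSE)
  i <- sowing:(anthesis - 1L)
  sum(at_fc[i] & tmean[i] >= tmean_min) > min_days
}

#' Lodging risk from heavy rain late in the season
#'
#' Window: anthesis to 5 days before maturity. A day qualifies with
#' precipitation > 40 mm, or > 20 mm when the soil was at or above field
#' capacity the previous day. True with at least 2 qualifying days.
#'
#' @param precip daily precipitation.
#' @param at_fc logical daily at-field-capacity flags.
#' @param anthesis,maturity day indices.
#' @return logical.
#' @export
detect_lodging_risk <- function(precip, at_fc, anthesis, maturity) {
  to <- maturity - 5L
  if (to < anthesis) return(FALSE)
  i <- anthesis:to
  prev_fc <- at_fc[pmax(i - 1L, 1L)]
  qual <- precip[i] > 40 | (precip[i] > 20 & prev_fc)
  sum(qual) >= 2
}

#' Extreme heat during grain filling
#'
#' True if tmax exceeds 35 degC on at least 3 (cumulative) days between 5
#' days after anthesis and maturity.
#'
#' @param tmax daily maxima.
#' @param anthesis,maturity day indices.
#' @param threshold temperature trigger (deg C).
#' @param min_days required day count.
#' @return logical.
#' @export
detect_grainfill_heat <- function(tmax, anthesis, maturity, threshold = 35,
                                  min_days = 3) {
  from <- anthesis + 5L
  if (from > maturity) return(FALSE)
  sum(tmax[from:maturity] > threshold) >= min_days
}

#' Adverse sowing conditions
#'
#' Window: sowing date +/- 15 days. A day is workable when the top-layer
#' relative saturation is strictly between 5% and 90%, rain that day is
#' below 5 mm and rain the preceding day at most 10 mm. True when fewer
#' than 3 days of the window are workable.
#'
#' @param rel_sat_top daily top-layer relative saturation (0-1).
#' @param precip daily precipitation.
#' @param sowing day index of the nominal sowing date.
#' @param min_workable workable-day threshold (event if count < 3).
#' @return logical.
#' @export
detect_adverse_sowing <- function(rel_sat_top, precip, sowing,
                                  min_workable = 3) {
  i <- max(sowing - 15L, 2L):(sowing + 15L)
  workable <- rel_sat_top[i] > 0.05 & rel_sat_top[i] < 0.90 &
    precip[i] < 5 & precip[i - 1L] <= 10
  sum(workable) < min_workable
}

#' Adverse harvest conditions
#'
#' Window: maturity + 5 to maturity + 25 days. A day is workable when
#' top-layer saturation is below 85%, rain that day below 0.5 mm and rain
#' the preceding day at most 5 mm. True when fewer than 3 days are
#' workable.
#'
#' @param rel_sat_top daily top-layer relative saturation (0-1).
#' @param precip daily precipitation.
#' @param maturity day index of maturity.
#' @param min_workable workable-day threshold.
#' @return logical.
#' @export
detect_adverse_harvest <- function(rel_sat_top, precip, maturity,
                                   min_workable = 3) {
  i <- (maturity + 5L):(maturity + 25L)
  workable <- rel_sat_top[i] < 0.85 & precip[i] < 0.5 & precip[i - 1L] <= 5
  sum(workable) < min_workable
}

#' Detect all seven adverse events for every crop season
#'
#' @param series weather_series.
#' @param soil water-balance trajectory from [run_water_balance()], aligned
#'   row-for-row with `series`.
#' @param pheno season table from [season_phenology()].
#' @return data.frame, one row per harvest year, logical columns
#'   `frost_no_snow`, `late_frost`, `wet_early_season`, `lodging_risk`,
#'   `grainfill_heat`, `adverse_sowing`, `adverse_harvest`.
#' @export
detect_adverse_events <- function(series, soil, pheno) {
  stopifnot(nrow(soil) == nrow(series))
  tmean <- (series$tmax + series$tmin) / 2
  n <- nrow(pheno)
  res <- data.frame(
    harvest_year = pheno$harvest_year,
    frost_no_snow = logical(n), late_frost = logical(n),
    wet_early_season = logical(n), lodging_risk = logical(n),
    grainfill_heat = logical(n), adverse_sowing = logical(n),
    adverse_harvest = logical(n))
  for (k in seq_len(n)) {
    sow <- pheno$sowing[k]; anth <- pheno$anthesis[k]; mat <- pheno$maturity[k]
    res$frost_no_snow[k] <- detect_frost_no_snow(series$tmin, soil$swe,
                                                 sow, mat)
    res$late_frost[k] <- detect_late_frost(tmean, series$tmin, sow, mat)
    res$wet_early_season[k] <- detect_wet_early_season(soil$at_fc, tmean,
                                                       sow, anth)
    res$lodging_risk[k] <- detect_lodging_risk(series$precip, soil$at_fc,
                                               anth, mat)
    res$grainfill_heat[k] <- detect_grainfill_heat(series$tmax, anth, mat)
    res$adverse_sowing[k] <- detect_adverse_sowing(soil$rel_sat_top,
                                                   series$precip, sow)
    res$adverse_harvest[k] <- detect_adverse_harvest(soil$rel_sat_top,
                                                     series$precip, mat)
  }
  res
}

#' Event occurrence probabilities
#'
#' Fraction of retained crop years in which each event occurred.
#'
#' @param flags data.frame from [detect_adverse_events()] (spin-up years
#'   already excluded upstream).
#' @return data.frame with `event`, `probability`, `n_years`.
#' @export
event_probability <- function(flags) {
  events <- setdiff(names(flags), "harvest_year")
  n <- nrow(flags)
  if (n < 1) stop("no retained crop years")
  data.frame(event = events,
             probability = vapply(events, function(e) mean(flags[[e]]),
                                  numeric(1)),
             n_years = n, row.names = NULL)
}
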