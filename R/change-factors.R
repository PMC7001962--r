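#' Monthly change-factor set for one climate-model scenario
#'
#' Additive monthly shifts of mean tmax/tmin (deg C) and multiplicative
#' monthly precipitation ratios, as derived from one global climate model for
#' one emissions scenario and period, plus the scenario CO2 concentration
#' carried as metadata (the crop model applies no CO2 physiology).
#'
#' @param gcm_id model label.
#' @param scenario e.g. `"RCP4.5"` or `"RCP8.5"`.
#' @param period e.g. `"2050"`.
#' @param dtmax,dtmin length-12 additive shifts (deg C).
#' @param precip_ratio length-12 multiplicative ratios (>= 0).
#' @param co2_ppm scenario CO2 (ppm); defaults from the scenario/period
#'   lookup in [scenario_co2()].
#' @return object of class `change_factor_set`.
#' @export
change_factor_set <- function(gcm_id, scenario, period, dtmax, dtmin,
                              precip_ratio,
                              co2_ppm = scenario_co2(scenario, period)) {
  stopifnot(length(dtmax) == 12, length(dtmin) == 12,
            length(precip_ratio) == 12)
  if (any(precip_ratio < 0)) stop("precip_ratio must be >= 0")
  structure(list(gcm_id = gcm_id, scenario = scenario, period = period,
                 dtmax = as.numeric(dtmax), dtmin = as.numeric(dtmin),
                 precip_ratio = as.numeric(precip_ratio),
                 co2_ppm = co2_ppm),
            class = "change_factor_set")
}

#' @export
print.change_factor_set <- function(x, ...) {
  cat(sprintf("<change_factor_set> %s %s %s: dT %.1f..%.1f degC, P ratio %.2f..%.2f, CO2 %s ppm\n",
              x$gcm_id, x$scenario, x$period, min(x$dtmax), max(x$dtmax),
              min(x$precip_ratio), max(x$precip_ratio), format(x$co2_ppm)))
  invisible(x)
}

#' Scenario CO2 concentrations (ppm)
#'
#' Baseline 1981-2010: 364 ppm. RCP4.5: 487 (2041-2060), 533 (2081-2100).
#' RCP8.5: 541 (2041-2060), 844 (2081-2100).
#'
#' @param scenario `"baseline"`, `"RCP4.5"` or `"RCP8.5"`.
#' @param period `"baseline"`, `"2050"` or `"2090"`.
#' @return CO2 concentration in ppm.
#' @export
scenario_co2 <- function(scenario, period = "2050") {
  if (identical(scenario, "baseline") || identical(period, "baseline"))
    return(364)
  tab <- c("RCP4.5.2050" = 487, "RCP4.5.2090" = 533,
           "RCP8.5.2050" = 541, "RCP8.5.2090" = 844)
  key <- paste(scenario, period, sep = ".")
  if (!key %in% names(tab)) return(NA_real_)
  unname(tab[key])
}

#' Neutral (identity) change-factor member
#' @param scenario,period labels for the neutral member.
#' @return `change_factor_set` with zero temperature shifts and unit ratios.
#' @export
neutral_change_factors <- function(scenario = "baseline",
                                   period = "baseline") {
  change_factor_set("neutral", scenario, period,
                    dtmax = rep(0, 12), dtmin = rep(0, 12),
                    precip_ratio = rep(1, 12))
}

#' Synthetic pseudo-GCM change-factor ensemble
#'
#' Emulates a 16-member climate-model ensemble for a UK mid-century scenario:
#' annual-mean warming between 0.2 and 3.0 degC (amplified in summer),
#' winter precipitation change between -10% and +40% and summer change
#' within +/-30%, smoothly interpolated across months. The first member is
#' pinned to the wet end of the winter envelope and the second to the dry
#' end, labelled `"wet"` and `"dry"` so range maps can use them directly.
#' With `n_members = 1` a single neutral member is returned.
#'
#' @param seed integer seed.
#' @param n_members ensemble size (default 16).
#' @param scenario,period labels (drive the CO2 metadata).
#' @return list of [change_factor_set()]s.
#' @export
make_synthetic_ensemble <- function(seed, n_members = 16,
                                    scenario = "RCP8.5", period = "2050") {
  stopifnot(n_members >= 1)
  if (n_members == 1)
    return(list(neutral_change_factors(scenario, period)))
  with_seed(seed, {
    warming <- stats::runif(n_members, 0.2, 3.0)
    amp <- stats::runif(n_members, 0, 0.4)        # summer amplification
    winter <- stats::runif(n_members, -0.10, 0.40)
    summer <- stats::runif(n_members, -0.30, 0.30)
    winter[1] <- 0.40; summer[1] <- 0.30          # designated wet member
    winter[2] <- -0.10; summer[2] <- -0.30        # designated dry member
    mo <- 1:12
    lapply(seq_len(n_members), function(i) {
      # cos term integrates to zero over the year -> annual mean = warming[i]
      dt <- warming[i] * (1 + amp[i] * cos(2 * pi * (mo - 7) / 12))
      # seasonal half-waves: winter change peaks in January, summer in July,
      # fading to no change at the equinoxes, so every month stays inside
      # the envelope of its own season
      wave <- cos(2 * pi * (mo - 1) / 12)
      ratio <- 1 + winter[i] * pmax(0, wave) + summer[i] * pmax(0, -wave)
      cf <- change_factor_set(sprintf("SYN%02d", i), scenario, period,
                              dtmax = dt, dtmin = dt,
                              precip_ratio = pmax(ratio, 0))
      cf$tag <- if (i == 1) "wet" else if (i == 2) "dry" else ""
      cf
    })
  })
}

#' Write an ensemble of change-factor sets to CSV
#'
#' Long format with columns `gcm`, `scenario`, `period`, `month`, `dtmax`,
#' `dtmin`, `precip_ratio`, `co2_ppm`.
#'
#' @param members list of `change_factor_set`.
#' @param path output CSV.
#' @export
write_change_factors <- function(members, path) {
  rows <- lapply(members, function(cf)
    data.frame(gcm = cf$gcm_id, scenario = cf$scenario, period = cf$period,
               month = 1:12, dtmax = cf$dtmax, dtmin = cf$dtmin,
               precip_ratio = cf$precip_ratio, co2_ppm = cf$co2_ppm))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read change-factor sets from CSV
#' @param path CSV written in the [write_change_factors()] layout.
#' @return list of `change_factor_set`.
#' @export
read_change_factors <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gcm", "scenario", "period", "month", "dtmax", "dtmin",
            "precip_ratio")
  if (!all(need %in% names(df)))
    stop("change-factor CSV needs columns: ", paste(need, collapse = ", "))
  keys <- unique(df[c("gcm", "scenario", "period")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- merge(keys[i, , drop = FALSE], df)
    sub <- sub[order(sub$month), ]
    if (!identical(as.integer(sub$month), 1:12))
      stop("change-factor set ", keys$gcm[i], " does not cover months 1-12")
    co2 <- if ("co2_ppm" %in% names(sub)) sub$co2_ppm[1] else
      scenario_co2(keys$scenario[i], keys$period[i])
    change_factor_set(keys$gcm[i], keys$scenario[i], keys$period[i],
                      sub$dtmax, sub$dtmin, sub$precip_ratio, co2)
  })
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
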