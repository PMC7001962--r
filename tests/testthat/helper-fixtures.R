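# Shared fixtures, built once per session and memoised. All synthetic, all
# seeded: nothing here reads from disk.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 120-year forced baseline series at the default (eastern) synthetic site,
# with both soil profiles, phenology and 100 retained crop years
fix_baseline <- function() memo("baseline", function() {
  clim <- synthetic_site_climatology()
  series <- compute_forcing(generate_series(clim, 120, seed = 42))
  soil180 <- run_water_balance(series, soil_profile("default180"))
  soil177 <- run_water_balance(series, soil_profile("hafren177"))
  pheno <- season_phenology(series)
  retained <- pheno[pheno$harvest_year > 20, , drop = FALSE]
  list(clim = clim, series = series, soil180 = soil180, soil177 = soil177,
       pheno = retained, spin_up = 20)
})

fix_flags <- function() memo("flags", function() {
  fx <- fix_baseline()
  detect_adverse_events(fx$series, fx$soil180, fx$pheno)
})

fix_yields <- function() memo("yields", function() {
  fx <- fix_baseline()
  simulate_yield_set(fx$series, fx$soil177, fx$pheno)
})

# Random synthetic crop-year slice for the detector/oracle comparisons:
# weather and soil states are drawn directly (not from the process models)
# so that rare triggers (deep frost, 40 mm rain, saturated topsoil) occur
# often enough to exercise every branch.
random_crop_year <- function(seed) {
  set.seed(seed)
  n <- 420L
  doy_shift <- 292L  # slice starts 1 day before a 20 Oct sowing
  tmean_cycle <- 9 - 7 * cos(2 * pi * ((seq_len(n) + doy_shift) %% 365) / 365)
  tmean <- tmean_cycle + stats::rnorm(n, 0, 6)
  half_range <- abs(stats::rnorm(n, 4, 2)) + 0.2
  tmax <- tmean + half_range
  tmin <- tmean - half_range
  # occasionally brutal frosts
  deep <- stats::runif(n) < 0.01
  tmin[deep] <- tmin[deep] - stats::runif(sum(deep), 5, 20)
  wet <- stats::runif(n) < 0.45
  precip <- ifelse(wet, stats::rgamma(n, 0.7, scale = 9), 0)
  heat <- stats::runif(n) < 0.02
  tmax[heat] <- tmax[heat] + stats::runif(sum(heat), 8, 20)
  swe <- ifelse(stats::runif(n) < 0.08, stats::runif(n, 0, 30), 0)
  rel_sat_top <- stats::runif(n)
  at_fc <- stats::runif(n) < 0.3
  sowing <- 2L + sample(0:10, 1)
  anthesis <- sowing + sample(200:250, 1)
  maturity <- anthesis + sample(40:60, 1)
  list(tmax = tmax, tmin = tmin, tmean = tmean, precip = precip, swe = swe,
       rel_sat_top = rel_sat_top, at_fc = at_fc, sowing = sowing,
       anthesis = anthesis, maturity = maturity, n = n)
}

MONTH_STARTS_TEST <- c(1L, 32L, 60L, 91L, 121L, 152L, 182L, 213L, 244L,
                       274L, 305L, 335L)

# constant-weather series builder for closed-form phenology cases
constant_series <- function(n_days, tmax, tmin, precip = 0, sun = 4,
                            latitude = 52) {
  doy <- ((seq_len(n_days) - 1L) %% 365L) + 1L
  m <- findInterval(doy, MONTH_STARTS_TEST)
  df <- data.frame(year = (seq_len(n_days) - 1L) %/% 365L + 1L,
                   month = m, day = doy - MONTH_STARTS_TEST[m] + 1L,
                   doy = doy,
                   tmax = rep_len(tmax, n_days), tmin = rep_len(tmin, n_days),
                   precip = rep_len(precip, n_days),
                   sun_hours = rep_len(sun, n_days))
  weather_series(df, site = list(name = "const", latitude = latitude),
                 validate = FALSE)
}
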