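# Hand-built season slices: 400 mild days, then each case perturbs the
# fields its trigger needs. Stage indices mimic a late-October sowing.
mild_year <- function() {
  n <- 400L
  list(tmax = rep(12, n), tmin = rep(4, n), tmean = rep(8, n),
       precip = rep(0, n), swe = rep(0, n), rel_sat_top = rep(0.5, n),
       at_fc = rep(FALSE, n), sowing = 20L, anthesis = 250L,
       maturity = 300L, n = n)
}

test_that("frost-without-snow needs both deep frost and a bare surface", {
  yr <- mild_year()
  expect_false(detect_frost_no_snow(yr$tmin, yr$swe, yr$sowing, yr$maturity))

  yr$tmin[60] <- -21
  expect_true(detect_frost_no_snow(yr$tmin, yr$swe, yr$sowing, yr$maturity))

  yr$swe[60] <- 50  # ~5 cm of snow insulates the crop
  expect_false(detect_frost_no_snow(yr$tmin, yr$swe, yr$sowing, yr$maturity))

  yr$swe[60] <- 0.5  # below the 1 cm depth equivalent
  expect_true(detect_frost_no_snow(yr$tmin, yr$swe, yr$sowing, yr$maturity))
})

test_that("late frost needs lost hardiness, which cool spells restore", {
  base <- mild_year()

  yr <- base
  yr$tmean[100:109] <- 11          # sustained warm spell (>= 5 days)
  yr$tmin[110] <- -3               # frost the day after it breaks
  expect_true(detect_late_frost(yr$tmean, yr$tmin, yr$sowing, yr$maturity))

  # a >2-day cool interruption re-hardens the crop before the frost
  yr2 <- base
  yr2$tmean[100:104] <- 11
  yr2$tmean[105:107] <- 6          # 3 cool days in a row
  yr2$tmin[110] <- -3
  expect_false(detect_late_frost(yr2$tmean, yr2$tmin, yr2$sowing,
                                 yr2$maturity))

  # 2 cool days are not enough to re-harden: frost on the second still hits
  yr3 <- base
  yr3$tmean[100:104] <- 11
  yr3$tmean[105:106] <- 6
  yr3$tmin[106] <- -3
  expect_true(detect_late_frost(yr3$tmean, yr3$tmin, yr3$sowing,
                                yr3$maturity))

  # only 4 warm days: hardiness never lost
  yr4 <- base
  yr4$tmean[100:103] <- 11
  yr4$tmin[110] <- -3
  expect_false(detect_late_frost(yr4$tmean, yr4$tmin, yr4$sowing,
                                 yr4$maturity))
})

test_that("wet early season counts warm at-capacity days, threshold strict", {
  yr <- mild_year()
  expect_false(detect_wet_early_season(yr$at_fc, yr$tmean, yr$sowing,
                                       yr$anthesis))

  yr$at_fc[30:90] <- TRUE  # 61 qualifying days
  expect_true(detect_wet_early_season(yr$at_fc, yr$tmean, yr$sowing,
                                      yr$anthesis))

  yr$at_fc <- rep(FALSE, yr$n)
  yr$at_fc[30:89] <- TRUE  # exactly 60: not an event
  expect_false(detect_wet_early_season(yr$at_fc, yr$tmean, yr$sowing,
                                       yr$anthesis))

  # 70 at-capacity days too cold to count
  yr$at_fc <- rep(FALSE, yr$n)
  yr$at_fc[30:99] <- TRUE
  yr$tmean[30:99] <- 2
  expect_false(detect_wet_early_season(yr$at_fc, yr$tmean, yr$sowing,
                                       yr$anthesis))

  # non-consecutive qualifying days accumulate
  yr <- mild_year()
  yr$at_fc[seq(30, 30 + 2 * 61, by = 2)] <- TRUE
  expect_true(detect_wet_early_season(yr$at_fc, yr$tmean, yr$sowing,
                                      yr$anthesis))
})

test_that("lodging needs two qualifying rain days late in the season", {
  yr <- mild_year()
  yr$precip[c(260, 270)] <- 45
  expect_true(detect_lodging_risk(yr$precip, yr$at_fc, yr$anthesis,
                                  yr$maturity))

  yr <- mild_year()
  yr$precip[260] <- 45
  expect_false(detect_lodging_risk(yr$precip, yr$at_fc, yr$anthesis,
                                   yr$maturity))

  # 25 mm on a day after saturated soil qualifies at the lower threshold
  yr <- mild_year()
  yr$precip[c(260, 270)] <- 25
  yr$at_fc[c(259, 269)] <- TRUE
  expect_true(detect_lodging_risk(yr$precip, yr$at_fc, yr$anthesis,
                                  yr$maturity))

  # same 25 mm days on dry soil do not qualify
  yr$at_fc[c(259, 269)] <- FALSE
  expect_false(detect_lodging_risk(yr$precip, yr$at_fc, yr$anthesis,
                                   yr$maturity))

  # the window closes 5 days before maturity
  yr <- mild_year()
  yr$precip[c(296, 298)] <- 45
  expect_false(detect_lodging_risk(yr$precip, yr$at_fc, yr$anthesis,
                                   yr$maturity))
})

test_that("grain-filling heat needs 3 hot days inside its window", {
  yr <- mild_year()
  yr$tmax[260:262] <- 36
  expect_true(detect_grainfill_heat(yr$tmax, yr$anthesis, yr$maturity))

  yr <- mild_year()
  yr$tmax[240:242] <- 36  # before anthesis + 5
  expect_false(detect_grainfill_heat(yr$tmax, yr$anthesis, yr$maturity))

  yr <- mild_year()
  yr$tmax[c(256, 270, 290)] <- 36  # cumulative, not consecutive
  expect_true(detect_grainfill_heat(yr$tmax, yr$anthesis, yr$maturity))

  yr <- mild_year()
  yr$tmax[260:261] <- 36
  expect_false(detect_grainfill_heat(yr$tmax, yr$anthesis, yr$maturity))
})

test_that("adverse sowing: saturated or rain-hit windows block fieldwork", {
  yr <- mild_year()
  expect_false(detect_adverse_sowing(yr$rel_sat_top, yr$precip, yr$sowing))

  yr$rel_sat_top[] <- 0.97  # permanently saturated
  expect_true(detect_adverse_sowing(yr$rel_sat_top, yr$precip, yr$sowing))

  # exactly 3 workable days: not an event
  yr$rel_sat_top[c(10, 20, 30)] <- 0.5
  expect_false(detect_adverse_sowing(yr$rel_sat_top, yr$precip, yr$sowing))

  # a 6 mm rain day is unworkable but one lost day leaves the window fine
  yr <- mild_year()
  yr$precip[20] <- 6
  expect_false(detect_adverse_sowing(yr$rel_sat_top, yr$precip, yr$sowing))

  # bone-dry topsoil (below 5%) is also unworkable
  yr <- mild_year()
  yr$rel_sat_top[] <- 0.02
  expect_true(detect_adverse_sowing(yr$rel_sat_top, yr$precip, yr$sowing))
})

test_that("adverse harvest: drizzle thresholds and prior-day rain", {
  yr <- mild_year()
  expect_false(detect_adverse_harvest(yr$rel_sat_top, yr$precip,
                                      yr$maturity))

  # 0.4 mm with dry soil and a dry prior day is still workable
  yr$precip[(yr$maturity + 5):(yr$maturity + 25)] <- 0.4
  expect_false(detect_adverse_harvest(yr$rel_sat_top, yr$precip,
                                      yr$maturity))

  # persistent 2 mm drizzle blocks harvest entirely
  yr$precip[(yr$maturity + 4):(yr$maturity + 25)] <- 2
  expect_true(detect_adverse_harvest(yr$rel_sat_top, yr$precip,
                                     yr$maturity))

  # saturated topsoil blocks harvest even without rain
  yr <- mild_year()
  yr$rel_sat_top[] <- 0.9
  expect_true(detect_adverse_harvest(yr$rel_sat_top, yr$precip,
                                     yr$maturity))
})

test_that("event probabilities are counting fractions", {
  flags <- data.frame(harvest_year = 1:250,
                      wet_early_season = c(rep(TRUE, 25), rep(FALSE, 225)))
  p <- event_probability(flags)
  expect_equal(p$probability, 0.10)
  expect_equal(p$n_years, 250)

  all_false <- data.frame(harvest_year = 1:10, late_frost = rep(FALSE, 10))
  expect_equal(event_probability(all_false)$probability, 0)
  all_true <- data.frame(harvest_year = 1:10, late_frost = rep(TRUE, 10))
  expect_equal(event_probability(all_true)$probability, 1)
  expect_error(event_probability(data.frame(harvest_year = integer(0),
                                            x = logical(0))),
               "no retained")

  # invariant to year ordering
  fx_flags <- fix_flags()
  shuffled <- fx_flags[sample(nrow(fx_flags)), ]
  expect_equal(event_probability(shuffled)$probability,
               event_probability(fx_flags)$probability)
})

test_that("detectors agree with naive day-by-day scans on random years", {
  for (seed in 1:300) {
    yr <- random_crop_year(seed)
    got <- package_detectors(yr)
    want <- naive_detectors(yr)
    if (!identical(got, want)) {
      fail(sprintf("disagreement at seed %d: %s", seed,
                   paste(names(got)[got != want], collapse = ", ")))
    }
  }
  succeed()
})

test_that("pipeline-level flags are plausible for a UK-like baseline", {
  pr <- event_probability(fix_flags())
  probs <- stats::setNames(pr$probability, pr$event)
  expect_equal(unname(probs["frost_no_snow"]), 0)       # UK winters too mild
  expect_equal(unname(probs["grainfill_heat"]), 0)      # 35 degC unreachable
  expect_lt(probs["late_frost"], 0.12)
  expect_true(all(pr$probability >= 0 & pr$probability <= 1))
})
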