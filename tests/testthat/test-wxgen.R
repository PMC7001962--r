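test_that("quality control flags impossible days and reports the fraction", {
  clim <- synthetic_site_climatology()
  s <- generate_series(clim, 12, seed = 3)
  df <- as.data.frame(s)

  # one inverted day: tmax 12 / tmin 15
  bad <- df
  bad$tmax[100] <- 12
  bad$tmin[100] <- 15
  out <- qc_series(weather_series(bad, series_site(s), validate = FALSE))
  rep <- qc_report(out)
  expect_equal(unname(rep$fraction_flagged["tmax"]), 1 / nrow(df))
  expect_true(out$tmax[100] >= out$tmin[100])
  expect_false(out$tmin[100] == 15)

  # clean series passes through identically
  clean <- qc_series(s)
  expect_equal(clean$tmax, s$tmax)
  expect_equal(clean$precip, s$precip)
  expect_equal(sum(qc_report(clean)$n_flagged), 0L)

  # a site with 12% missing precipitation is rejected
  miss <- df
  drop <- seq_len(floor(0.12 * nrow(df)))
  miss$precip[drop] <- NA
  expect_error(
    qc_series(weather_series(miss, series_site(s), validate = FALSE)),
    "rejected")
})

test_that("weather CSV round-trips and unparseable dates report the line", {
  s <- generate_series(synthetic_site_climatology(), 2, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_weather_csv(s, path)
  back <- read_weather_csv(path, series_site(s))
  expect_equal(back$precip, s$precip, tolerance = 1e-6)
  expect_equal(back$tmax, s$tmax, tolerance = 1e-6)

  lines <- readLines(path)
  lines[5] <- sub("^[0-9-]+", "not-a-date", lines[5])
  writeLines(lines, path)
  expect_error(read_weather_csv(path, series_site(s)), "line 5")
})

test_that("generation is deterministic and respects physical invariants", {
  clim <- synthetic_site_climatology()
  a <- generate_series(clim, 20, seed = 99)
  b <- generate_series(clim, 20, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(a$precip, generate_series(clim, 20, seed = 100)$precip))

  for (seed in c(1, 2, 3)) {
    g <- generate_series(clim, 10, seed = seed)
    expect_true(all(g$tmax >= g$tmin))
    expect_true(all(g$precip >= 0))
    N <- daylength(52, g$doy)
    expect_true(all(g$sun_hours >= 0 & g$sun_hours <= N + 1e-9))
  }
})

test_that("fitted climatology recovers the generating parameters", {
  truth <- synthetic_site_climatology()
  s <- generate_series(truth, 500, seed = 314)
  fit <- fit_climatology(s)
  expect_equal(fit$params$p_ww, truth$params$p_ww, tolerance = 0.03)
  expect_equal(fit$params$p_wd, truth$params$p_wd, tolerance = 0.03)
  # gamma moments: compare the implied monthly totals (shape/scale trade off)
  expect_equal(expected_monthly_precip(fit), expected_monthly_precip(truth),
               tolerance = 0.05)
  expect_equal(fit$params$tmax_mean_dry, truth$params$tmax_mean_dry,
               tolerance = 0.02)
  expect_equal(fit$params$tmin_mean_wet, truth$params$tmin_mean_wet,
               tolerance = 0.05)
})

test_that("constant weather fits to degenerate parameters", {
  s <- constant_series(365 * 12, tmax = 15, tmin = 5)
  expect_warning(expect_warning(fit <- fit_climatology(s), "shape"),
                 "scale")
  expect_true(all(fit$params$p_wd == 0))
  expect_true(all(fit$params$p_ww == 0))
  expect_true(all(fit$params$tmax_sd_dry == 0))
  expect_equal(fit$params$tmax_mean_dry, rep(15, 12))
})

test_that("fit requires ten whole years", {
  s <- generate_series(synthetic_site_climatology(), 9, seed = 1)
  expect_error(fit_climatology(s), "10 whole")
})

test_that("fit/generate round-trip reproduces monthly mean tmax within 0.2 degC", {
  obs <- generate_series(synthetic_site_climatology(), 30, seed = 11)
  fit <- fit_climatology(obs)
  regen <- generate_series(fit, 500, seed = 12)
  obs_monthly <- tapply(obs$tmax, obs$month, mean)
  regen_monthly <- tapply(regen$tmax, regen$month, mean)
  expect_lt(max(abs(obs_monthly - regen_monthly)), 0.2)
})

test_that("neutral change factors are the identity on all parameters", {
  clim <- synthetic_site_climatology()
  out <- apply_change_factors(clim, neutral_change_factors())
  expect_equal(out$params, clim$params)
})

test_that("perturbed climatology scales expected precipitation exactly", {
  clim <- synthetic_site_climatology()
  set.seed(8)
  ratio <- stats::runif(12, 0.5, 1.6)
  cf <- change_factor_set("x", "RCP8.5", "2050", dtmax = stats::rnorm(12),
                          dtmin = stats::rnorm(12), precip_ratio = ratio)
  pert <- apply_change_factors(clim, cf)
  expect_equal(expected_monthly_precip(pert),
               ratio * expected_monthly_precip(clim), tolerance = 1e-12)
  expect_error(change_factor_set("x", "s", "p", rep(0, 12), rep(0, 12),
                                 precip_ratio = c(-0.1, rep(1, 11))),
               ">= 0")
})

test_that("change-factor perturbations propagate into paired generated series", {
  clim <- synthetic_site_climatology()
  base <- generate_series(clim, 200, seed = 77)

  # +3 degC tmax in August shifts generated August tmax by exactly +3
  dtx <- rep(0, 12); dtx[8] <- 3
  cf_t <- change_factor_set("t", "RCP8.5", "2050", dtx, rep(0, 12), rep(1, 12))
  warm <- generate_series(apply_change_factors(clim, cf_t), 200, seed = 77)
  aug <- base$month == 8
  expect_equal(warm$tmax[aug], base$tmax[aug] + 3, tolerance = 1e-9)
  expect_equal(warm$tmax[!aug], base$tmax[!aug], tolerance = 1e-9)

  # July ratio 0.8 scales generated July precipitation by ~0.8
  pr <- rep(1, 12); pr[7] <- 0.8
  cf_p <- change_factor_set("p", "RCP8.5", "2050", rep(0, 12), rep(0, 12), pr)
  drier <- generate_series(apply_change_factors(clim, cf_p), 200, seed = 77)
  jul <- base$month == 7
  expect_equal(sum(drier$precip[jul]) / sum(base$precip[jul]), 0.8,
               tolerance = 0.01)
  expect_equal(drier$precip[!jul], base$precip[!jul])
})

test_that("synthetic ensemble spans the projection envelope", {
  members <- make_synthetic_ensemble(seed = 123, n_members = 16)
  expect_length(members, 16)
  expect_length(unique(vapply(members, `[[`, "", "gcm_id")), 16)
  winter <- c(12, 1, 2)
  summer <- 6:8
  for (cf in members) {
    expect_true(mean(cf$dtmax) >= 0.2 - 1e-9)
    expect_true(mean(cf$dtmax) <= 3.0 + 1e-9)
    expect_true(all(cf$precip_ratio[winter] >= 0.9 - 1e-9))
    expect_true(all(cf$precip_ratio[winter] <= 1.4 + 1e-9))
    expect_true(all(cf$precip_ratio[summer] >= 0.7 - 1e-9))
    expect_true(all(cf$precip_ratio[summer] <= 1.3 + 1e-9))
    expect_equal(cf$co2_ppm, 541)  # RCP8.5 mid-century
  }
  expect_equal(members[[1]]$tag, "wet")
  expect_equal(members[[2]]$tag, "dry")
  expect_gt(mean(members[[1]]$precip_ratio[winter]),
            mean(members[[2]]$precip_ratio[winter]))

  single <- make_synthetic_ensemble(seed = 1, n_members = 1)
  expect_length(single, 1)
  expect_equal(single[[1]]$precip_ratio, rep(1, 12))
  expect_equal(single[[1]]$dtmax, rep(0, 12))
})

test_that("change-factor CSV round-trips", {
  members <- make_synthetic_ensemble(seed = 4, n_members = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_change_factors(members, path)
  back <- read_change_factors(path)
  expect_length(back, 3)
  ids <- vapply(back, `[[`, "", "gcm_id")
  orig <- members[[match("SYN02", ids)]]
  rb <- back[[which(ids == "SYN02")]]
  expect_equal(rb$dtmax, orig$dtmax, tolerance = 1e-9)
  expect_equal(rb$precip_ratio, orig$precip_ratio, tolerance = 1e-9)
  expect_equal(rb$co2_ppm, orig$co2_ppm)
})
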