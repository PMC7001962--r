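test_that("water stress factor is the clipped ETa/ET0 ratio", {
  expect_equal(water_stress_factor(3, 3), 1)
  expect_equal(water_stress_factor(0, 5), 0)
  expect_equal(water_stress_factor(2, 5), 0.4)
  expect_equal(water_stress_factor(4, 0), 1)   # no demand, no stress
  expect_equal(water_stress_factor(6, 5), 1)   # clipped from above
})

test_that("drought grain factor: 0.9 threshold over the flowering window", {
  n <- 400
  ratio <- rep(1, n)
  expect_equal(drought_grain_factor(ratio, anthesis = 200), 1)

  ratio[195] <- 0.45                       # one bad day halves grain number
  expect_equal(drought_grain_factor(ratio, anthesis = 200), 0.5)

  ratio <- rep(0.95, n)                    # above threshold everywhere
  expect_equal(drought_grain_factor(ratio, anthesis = 200), 1)

  ratio <- rep(1, n)                       # stress outside -10..+5 is ignored
  ratio[c(189, 206)] <- 0.1
  expect_equal(drought_grain_factor(ratio, anthesis = 200), 1)
  ratio[190] <- 0.45
  expect_equal(drought_grain_factor(ratio, anthesis = 200), 0.5)
})

test_that("heat sterility factor: 30 degC threshold in two windows", {
  n <- 400
  tmax <- rep(25, n)
  expect_equal(heat_sterility_factor(tmax, anthesis = 200), 1)

  tmax[198] <- 32                          # 2 degC excess, slope 0.05
  expect_equal(heat_sterility_factor(tmax, anthesis = 200), 0.9)

  tmax <- rep(25, n)
  tmax[c(202, 203, 204, 213)] <- 36        # gap days and post-window ignored
  expect_equal(heat_sterility_factor(tmax, anthesis = 200), 1)

  tmax <- rep(25, n)
  tmax[207] <- 36                          # day +7: in the grain-set window
  expect_equal(heat_sterility_factor(tmax, anthesis = 200), 0.7)

  tmax <- rep(25, n)
  tmax[195] <- 52                          # sterile fraction clips at 1
  expect_equal(heat_sterility_factor(tmax, anthesis = 200), 0)
})

test_that("potential-mode yield ignores the precipitation stream", {
  fx <- fix_baseline()
  s <- fx$series
  ph <- fx$pheno[1, ]
  cfg <- crop_run_config(water_mode = "potential")
  y1 <- simulate_crop(s, fx$soil177, ph, cfg = cfg)

  s2 <- as.data.frame(s)
  s2$precip <- 0 * s2$precip
  s2 <- weather_series(s2, series_site(s), validate = FALSE)
  dry_soil <- run_water_balance(s2, soil_profile("hafren177"), et0 = s$et0)
  y2 <- simulate_crop(s2, dry_soil, ph, cfg = cfg)
  expect_identical(y1, y2)
})

test_that("a stress-free season is yield-neutral and variants coincide", {
  fx <- fix_baseline()
  s <- fx$series
  ph <- fx$pheno[1, ]
  # synthetic stress-free trajectory: ETa == ET0 every day
  lush <- fx$soil177
  lush$eta <- s$et0
  y_pot <- simulate_crop(s, lush, ph, cfg = crop_run_config(water_mode = "potential"))
  y_w <- simulate_crop(s, lush, ph, cfg = crop_run_config(water_mode = "rainfed"))
  expect_identical(y_w, y_pot)   # WSI = 0 in the stress-free limit

  # tolerant and drought-sensitive coincide when no window day dips below 0.9
  f <- water_stress_factor(fx$soil177$eta, s$et0)
  stress_free_years <- fx$pheno[
    vapply(seq_len(nrow(fx$pheno)), function(k) {
      w <- (fx$pheno$anthesis[k] - 10):(fx$pheno$anthesis[k] + 5)
      all(f[w] >= 0.9)
    }, logical(1)), , drop = FALSE]
  expect_gt(nrow(stress_free_years), 0)
  ph0 <- stress_free_years[1, ]
  y_tol <- simulate_crop(s, fx$soil177, ph0,
                         cfg = crop_run_config(variant = "tolerant"))
  y_ds <- simulate_crop(s, fx$soil177, ph0,
                        cfg = crop_run_config(variant = "drought_sensitive"))
  expect_identical(y_ds, y_tol)
})

test_that("yield ordering invariants hold for every simulated year", {
  ys <- fix_yields()
  expect_true(all(ys$Y >= 0))
  expect_true(all(ys$Ywh >= 0))
  expect_true(all(ys$Ywh <= ys$Yw + 1e-12))
  expect_true(all(ys$Ywd <= ys$Yw + 1e-12))
  expect_true(all(ys$Yw <= ys$Y + 1e-12))
})

test_that("the calibration fixture yields about 8 t/ha unstressed", {
  ys <- fix_yields()
  expect_gt(mean(ys$Y), 6.5)
  expect_lt(mean(ys$Y), 9.5)
})

test_that("stress indices follow their defining ratios and bounds", {
  direct <- compute_stress_indices(
    data.frame(harvest_year = 1, Y = 12, Yw = 10, Ywd = 8, Ywh = 9))
  expect_equal(direct$per_year$HSI, 0.1)
  expect_equal(direct$per_year$DSI, 0.2)
  expect_equal(direct$per_year$WSI, 1 - 10 / 12)

  zero_den <- compute_stress_indices(
    data.frame(harvest_year = 1, Y = 0, Yw = 0, Ywd = 0, Ywh = 0))
  expect_equal(unlist(zero_den$per_year[-1]), c(HSI = 0, DSI = 0, WSI = 0))

  no_water_limit <- compute_stress_indices(
    data.frame(harvest_year = 1:30, Y = 8, Yw = 8, Ywd = 8, Ywh = 8))
  expect_equal(no_water_limit$summary$mean, rep(0, 3))
  expect_equal(no_water_limit$summary$p95, rep(0, 3))

  si <- compute_stress_indices(fix_yields())
  expect_true(all(si$per_year$HSI >= 0 & si$per_year$HSI <= 1))
  expect_true(all(si$per_year$DSI >= 0 & si$per_year$DSI <= 1))
  expect_true(all(si$per_year$WSI >= 0 & si$per_year$WSI <= 1))
  # 95th percentile is at least the median
  expect_gte(si$summary$p95[3], stats::median(si$per_year$WSI))
})

test_that("95th percentiles match a sort-based oracle", {
  si <- compute_stress_indices(fix_yields())
  expect_equal(si$summary$p95[2], percentile_oracle(si$per_year$DSI, 0.95))
  expect_equal(si$summary$p95[3], percentile_oracle(si$per_year$WSI, 0.95))
  set.seed(31)
  x <- stats::rbeta(250, 0.5, 4)
  expect_equal(unname(stats::quantile(x, 0.95, type = 7)),
               percentile_oracle(x, 0.95))
})

test_that("the light soil is never less stressed than the medium soil", {
  fx <- fix_baseline()
  soil127 <- run_water_balance(fx$series, soil_profile("light127"))
  ys177 <- fix_yields()
  ys127 <- simulate_yield_set(fx$series, soil127, fx$pheno)
  si177 <- compute_stress_indices(ys177)$summary
  si127 <- compute_stress_indices(ys127)$summary
  expect_gte(si127$mean[3], si177$mean[3])  # WSI
  expect_gte(si127$mean[2], si177$mean[2])  # DSI
})
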