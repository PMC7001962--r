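#' Monthly site climatology driving the weather generator
#'
#' Houses, per calendar month: wet-day transition probabilities (`p_wd` =
#' P(wet | previous day dry), `p_ww` = P(wet | previous day wet)), gamma
#' shape/scale of wet-day precipitation (mm), mean/sd of tmax and tmin
#' conditioned on wet and dry days (deg C), and mean/sd of the sunshine
#' fraction (sun hours / daylength) conditioned on wet and dry days.
#' `temp_ar1` is the lag-1 autocorrelation of the standardised daily
#' temperature residual and `temp_cross_cor` the tmax/tmin residual
#' correlation; both are generation parameters rather than fitted monthly
#' statistics.
#'
#' @param params data.frame with 12 rows and columns `month`, `p_wd`, `p_ww`,
#'   `shape`, `scale`, `tmax_mean_dry`, `tmax_sd_dry`, `tmax_mean_wet`,
#'   `tmax_sd_wet`, `tmin_mean_dry`, `tmin_sd_dry`, `tmin_mean_wet`,
#'   `tmin_sd_wet`, `sun_mean_dry`, `sun_sd_dry`, `sun_mean_wet`,
#'   `sun_sd_wet`.
#' @param site site metadata list (`name`, `latitude`, `elevation`).
#' @param wet_threshold precipitation (mm) at or above which a day is wet.
#' @param temp_ar1 day-to-day autocorrelation of temperature residuals.
#' @param temp_cross_cor correlation between tmax and tmin residuals.
#' @return object of class `site_climatology`.
#' @export
site_climatology <- function(params, site, wet_threshold = 0.1,
                             temp_ar1 = 0.6, temp_cross_cor = 0.8) {
  need <- c("month", "p_wd", "p_ww", "shape", "scale",
            "tmax_mean_dry", "tmax_sd_dry", "tmax_mean_wet", "tmax_sd_wet",
            "tmin_mean_dry", "tmin_sd_dry", "tmin_mean_wet", "tmin_sd_wet",
            "sun_mean_dry", "sun_sd_dry", "sun_mean_wet", "sun_sd_wet")
  stopifnot(is.data.frame(params), nrow(params) == 12,
            all(need %in% names(params)), identical(params$month, 1:12))
  if (is.null(site$elevation)) site$elevation <- 50
  x <- structure(list(params = params[need], site = site,
                      wet_threshold = wet_threshold, temp_ar1 = temp_ar1,
                      temp_cross_cor = temp_cross_cor),
                 class = "site_climatology")
  validate_climatology(x)
  x
}

validate_climatology <- function(x) {
  p <- x$params
  probs <- c(p$p_wd, p$p_ww)
  if (any(probs < 0 | probs > 1)) stop("transition probabilities outside [0,1]")
  if (any(p$shape <= 0) || any(p$scale <= 0))
    stop("precipitation shape and scale must be > 0")
  sds <- unlist(p[grep("_sd_", names(p))])
  if (any(sds < 0)) stop("negative standard deviation in climatology")
  if (abs(x$temp_ar1) >= 1) stop("temp_ar1 must be in (-1, 1)")
  if (abs(x$temp_cross_cor) > 1) stop("temp_cross_cor must be in [-1, 1]")
  invisible(x)
}

#' @export
print.site_climatology <- function(x, ...) {
  cat(sprintf("<site_climatology> %s (lat %.2f), wet threshold %.2f mm\n",
              if (is.null(x$site$name)) "site" else x$site$name,
              x$site$latitude, x$wet_threshold))
  ep <- expected_monthly_precip(x)
  cat(sprintf("  expected annual precip %.0f mm; Jan tmax %.1f / tmin %.1f degC\n",
              sum(ep), month_mean(x, "tmax")[1], month_mean(x, "tmin")[1]))
  invisible(x)
}

# stationary wet-day probability of the two-state chain, per month
stationary_wet_prob <- function(clim) {
  p <- clim$params
  denom <- 1 - p$p_ww + p$p_wd
  ifelse(denom > 0, p$p_wd / denom, 1)
}

#' Expected monthly precipitation implied by a climatology
#'
#' Days-in-month x stationary wet-day probability x gamma mean. This is the
#' quantity the change-factor precipitation ratio scales exactly.
#'
#' @param clim site_climatology.
#' @return numeric vector of 12 monthly totals (mm).
#' @export
expected_monthly_precip <- function(clim) {
  p <- clim$params
  MONTH_LENGTHS * stationary_wet_prob(clim) * p$shape * p$scale
}

# wet/dry-weighted unconditional monthly mean of tmax or tmin
month_mean <- function(clim, var = c("tmax", "tmin")) {
  var <- match.arg(var)
  pw <- stationary_wet_prob(clim)
  p <- clim$params
  pw * p[[paste0(var, "_mean_wet")]] + (1 - pw) * p[[paste0(var, "_mean_dry")]]
}

#' Fit a site climatology from daily weather
#'
#' Moment estimators throughout: transition probabilities are conditional
#' relative frequencies by month of the current day; wet-day gamma parameters
#' come from the method of moments (shape = mean^2/var, scale = var/mean);
#' temperature and sunshine-fraction moments are computed separately on wet
#' and dry days. A month with fewer than two wet days borrows precipitation
#' parameters from its calendar neighbours with a warning.
#'
#' @param series quality-controlled `weather_series` covering at least 10
#'   whole years.
#' @param wet_threshold wet-day precipitation threshold (mm).
#' @param temp_ar1,temp_cross_cor generation parameters passed through to
#'   [site_climatology()].
#' @return `site_climatology`.
#' @export
fit_climatology <- function(series, wet_threshold = 0.1,
                            temp_ar1 = 0.6, temp_cross_cor = 0.8) {
  df <- as.data.frame(series)
  n_years <- nrow(df) / DAYS_PER_YEAR
  if (n_years < 10 || nrow(df) %% DAYS_PER_YEAR != 0)
    stop("fit_climatology needs at least 10 whole 365-day years")
  site <- series_site(series)
  wet <- df$precip >= wet_threshold
  prev_wet <- c(NA, wet[-length(wet)])
  m <- df$month

  if (!("sun_hours" %in% names(df))) {
    # invert the Angstrom relation when only radiation was recorded
    ra <- extraterrestrial_radiation(site$latitude, df$doy)
    sun_frac <- pmin(pmax((df$radiation / ra$Ra - 0.25) / 0.50, 0), 1)
  } else {
    N <- daylength(site$latitude, df$doy)
    sun_frac <- pmin(pmax(df$sun_hours / N, 0), 1)
  }

  cond_stat <- function(x, cond, fun) {
    out <- vapply(1:12, function(mm) {
      v <- x[m == mm & cond]
      if (length(v) < 2) NA_real_ else fun(v)
    }, numeric(1))
    out
  }
  fill_adjacent <- function(v, what, fallback = 1) {
    if (!anyNA(v)) return(v)
    warning("borrowing ", what, " from adjacent months for month(s) ",
            paste(which(is.na(v)), collapse = ", "))
    for (mm in which(is.na(v))) {
      neigh <- c(v[(mm - 2) %% 12 + 1], v[mm %% 12 + 1])
      v[mm] <- mean(neigh, na.rm = TRUE)
    }
    if (anyNA(v)) v[is.na(v)] <- mean(v, na.rm = TRUE)
    # a series with no wet day anywhere: parameters unidentifiable, but the
    # wet-day probability is 0 so any positive placeholder is inert
    v[!is.finite(v)] <- fallback
    v
  }

  ok <- !is.na(prev_wet)
  p_wd <- vapply(1:12, function(mm) {
    i <- ok & m == mm & !prev_wet
    if (!any(i)) 0 else mean(wet[i])
  }, numeric(1))
  p_ww <- vapply(1:12, function(mm) {
    i <- ok & m == mm & prev_wet
    if (!any(i)) 0 else mean(wet[i])
  }, numeric(1))

  amt_mean <- cond_stat(df$precip, wet, mean)
  amt_var <- cond_stat(df$precip, wet, stats::var)
  shape <- amt_mean^2 / amt_var
  scale <- amt_var / amt_mean
  degen <- !is.na(amt_var) & amt_var <= 0
  shape[degen] <- NA; scale[degen] <- NA
  shape <- fill_adjacent(shape, "precipitation shape")
  scale <- fill_adjacent(scale, "precipitation scale")

  stat_pair <- function(x, cond) {
    mu <- cond_stat(x, cond, mean)
    sd <- cond_stat(x, cond, stats::sd)
    # months with no wet (or dry) days: fall back to the other condition
    mu_all <- vapply(1:12, function(mm) mean(x[m == mm]), numeric(1))
    sd_all <- vapply(1:12, function(mm) stats::sd(x[m == mm]), numeric(1))
    mu[is.na(mu)] <- mu_all[is.na(mu)]
    sd[is.na(sd)] <- sd_all[is.na(sd)]
    sd[is.na(sd)] <- 0
    list(mean = mu, sd = sd)
  }
  tx_d <- stat_pair(df$tmax, !wet); tx_w <- stat_pair(df$tmax, wet)
  tn_d <- stat_pair(df$tmin, !wet); tn_w <- stat_pair(df$tmin, wet)
  sf_d <- stat_pair(sun_frac, !wet); sf_w <- stat_pair(sun_frac, wet)

  params <- data.frame(
    month = 1:12, p_wd = p_wd, p_ww = p_ww, shape = shape, scale = scale,
    tmax_mean_dry = tx_d$mean, tmax_sd_dry = tx_d$sd,
    tmax_mean_wet = tx_w$mean, tmax_sd_wet = tx_w$sd,
    tmin_mean_dry = tn_d$mean, tmin_sd_dry = tn_d$sd,
    tmin_mean_wet = tn_w$mean, tmin_sd_wet = tn_w$sd,
    sun_mean_dry = sf_d$mean, sun_sd_dry = sf_d$sd,
    sun_mean_wet = sf_w$mean, sun_sd_wet = sf_w$sd)
  site_climatology(params, site, wet_threshold, temp_ar1, temp_cross_cor)
}

#' Perturb a climatology with monthly change factors
#'
#' Monthly tmax/tmin means (wet- and dry-day) are shifted additively; the
#' wet-day gamma scale is multiplied by the precipitation ratio, so the
#' expected monthly precipitation scales exactly by that ratio while wet-day
#' occurrence, variability shape and temperature variances are unchanged.
#'
#' @param base site_climatology.
#' @param cf [change_factor_set()].
#' @return perturbed `site_climatology` carrying the scenario as attributes.
#' @export
apply_change_factors <- function(base, cf) {
  stopifnot(inherits(base, "site_climatology"),
            inherits(cf, "change_factor_set"))
  if (any(cf$precip_ratio < 0)) stop("precip_ratio must be >= 0")
  p <- base$params
  p$tmax_mean_dry <- p$tmax_mean_dry + cf$dtmax
  p$tmax_mean_wet <- p$tmax_mean_wet + cf$dtmax
  p$tmin_mean_dry <- p$tmin_mean_dry + cf$dtmin
  p$tmin_mean_wet <- p$tmin_mean_wet + cf$dtmin
  ratio <- pmax(cf$precip_ratio, 1e-9)  # scale > 0 invariant; ratio 0 ~ no rain
  p$scale <- p$scale * ratio
  out <- site_climatology(p, base$site, base$wet_threshold,
                          base$temp_ar1, base$temp_cross_cor)
  attr(out, "scenario") <- list(gcm_id = cf$gcm_id, scenario = cf$scenario,
                                period = cf$period, co2_ppm = cf$co2_ppm)
  out
}

#' Synthetic UK-like site climatology
#'
#' Stands in for a climatology fitted to an observed UK station record:
#' seasonal cycles, first-order wet/dry persistence, skewed (gamma) daily
#' rainfall and wet/dry-conditioned temperatures. Variants shift the rainfall
#' regime: `"default"` is an eastern-England arable site (~650 mm/yr),
#' `"wet"` a western site (~1050 mm/yr) and `"dry"` a drier East Anglian one
#' (~560 mm/yr).
#'
#' @param name site label.
#' @param latitude degrees north.
#' @param variant `"default"`, `"wet"` or `"dry"`.
#' @param elevation m a.s.l.
#' @return `site_climatology`.
#' @export
synthetic_site_climatology <- function(name = "synth-east", latitude = 52,
                                       variant = c("default", "wet", "dry"),
                                       elevation = 50) {
  variant <- match.arg(variant)
  mo <- 1:12
  # smooth seasonal cycles typical of lowland southern-central England
  tmax <- 14.5 - 7.5 * cos(2 * pi * (mo - 1.5) / 12)
  tmin <- 7.0 - 5.5 * cos(2 * pi * (mo - 1.5) / 12)
  precip_month <- switch(variant,
    default = 55 + 12 * cos(2 * pi * (mo - 0.5) / 12),   # winter-peaked
    wet     = 88 + 30 * cos(2 * pi * (mo - 0.5) / 12),
    dry     = 47 + 8 * cos(2 * pi * (mo - 0.5) / 12))
  p_ww <- switch(variant,
    default = 0.62 + 0.06 * cos(2 * pi * (mo - 0.5) / 12),
    wet     = 0.70 + 0.06 * cos(2 * pi * (mo - 0.5) / 12),
    dry     = 0.58 + 0.06 * cos(2 * pi * (mo - 0.5) / 12))
  p_wd <- switch(variant,
    default = 0.32 + 0.05 * cos(2 * pi * (mo - 0.5) / 12),
    wet     = 0.40 + 0.05 * cos(2 * pi * (mo - 0.5) / 12),
    dry     = 0.28 + 0.05 * cos(2 * pi * (mo - 0.5) / 12))
  pi_wet <- p_wd / (1 - p_ww + p_wd)
  wet_day_mean <- precip_month / (MONTH_LENGTHS * pi_wet)
  shape <- rep(0.8, 12)                 # strongly right-skewed daily amounts
  scale <- wet_day_mean / shape
  sun_dry <- 0.42 + 0.12 * cos(2 * pi * (mo - 7) / 12)
  sun_wet <- 0.15 + 0.05 * cos(2 * pi * (mo - 7) / 12)
  params <- data.frame(
    month = mo, p_wd = p_wd, p_ww = p_ww, shape = shape, scale = scale,
    tmax_mean_dry = tmax + 0.8, tmax_sd_dry = 3.0,
    tmax_mean_wet = tmax - 1.0, tmax_sd_wet = 2.6,
    tmin_mean_dry = tmin - 0.8, tmin_sd_dry = 3.0,
    tmin_mean_wet = tmin + 0.5, tmin_sd_wet = 2.6,
    sun_mean_dry = sun_dry, sun_sd_dry = 0.18,
    sun_mean_wet = sun_wet, sun_sd_wet = 0.10)
  site_climatology(params,
                   list(name = name, latitude = latitude,
                        elevation = elevation, variant = variant))
}
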