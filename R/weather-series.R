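#' Construct a daily weather series
#'
#' A `weather_series` is a data.frame with one row per day on a 365-day
#' calendar, columns `year`, `month`, `day`, `doy`, `tmax`, `tmin`, `precip`
#' and at least one of `sun_hours` / `radiation`. Site metadata (name,
#' latitude, elevation) travel as an attribute so downstream radiation and
#' evapotranspiration steps need no extra arguments.
#'
#' @param df data.frame with the columns above.
#' @param site list with `name`, `latitude` (degrees, required), `elevation`
#'   (m, default 50).
#' @param seed integer seed the series was generated from, or `NA` for
#'   observed data.
#' @param validate check invariants (contiguous days, tmax >= tmin,
#'   precip >= 0). Generated series satisfy them by construction.
#' @return object of class `weather_series`.
#' @export
weather_series <- function(df, site, seed = NA_integer_, validate = TRUE) {
  stopifnot(is.data.frame(df), is.list(site), !is.null(site$latitude))
  if (is.null(site$elevation)) site$elevation <- 50
  need <- c("year", "month", "day", "doy", "tmax", "tmin", "precip")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("weather series lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!("sun_hours" %in% names(df)) && !("radiation" %in% names(df)))
    stop("weather series needs sun_hours or radiation")
  if (validate) {
    if (anyNA(df[need]))
      stop("weather series contains missing values; run qc_series() first")
    if (any(df$tmax < df$tmin)) stop("tmax < tmin in weather series")
    if (any(df$precip < 0)) stop("negative precipitation in weather series")
    off <- which(df$doy != ((df$doy[1] + seq_len(nrow(df)) - 2L) %% 365L) + 1L)
    if (length(off))
      stop("non-contiguous days in weather series at row ", off[1])
  }
  structure(df,
            class = c("weather_series", "data.frame"),
            site = site, seed = seed)
}

#' @export
print.weather_series <- function(x, ...) {
  s <- attr(x, "site")
  cat(sprintf("<weather_series> %s: %d days (%.1f years), lat %.2f\n",
              if (is.null(s$name)) "site" else s$name,
              nrow(x), nrow(x) / DAYS_PER_YEAR, s$latitude))
  cat(sprintf("  years %d-%d; seed %s\n", min(x$year), max(x$year),
              format(attr(x, "seed"))))
  invisible(x)
}

#' Site metadata of a weather series
#' @param x weather_series.
#' @return list with name, latitude, elevation.
#' @export
series_site <- function(x) attr(x, "site")

#' Read a daily weather CSV
#'
#' Expects columns `date` (ISO-8601), `tmax`, `tmin`, `precip` and
#' `sun_hours` and/or `radiation`. 29 February rows are dropped so that every
#' year has 365 days. Unparseable dates are a hard error reporting the
#' offending line.
#'
#' @param path CSV file.
#' @param site site metadata list (see [weather_series()]).
#' @return `weather_series` (not yet quality-controlled; may contain NA).
#' @export
read_weather_csv <- function(path, site) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!("date" %in% names(raw))) stop("no 'date' column in ", path)
  d <- as.Date(raw$date, format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(raw$date) & nzchar(raw$date))
  if (length(bad))
    stop("unparseable date at line ", bad[1] + 1L, " of ", path,
         ": '", raw$date[bad[1]], "'")
  if (anyNA(d)) stop("empty date field in ", path)
  mon <- as.integer(format(d, "%m"))
  day <- as.integer(format(d, "%d"))
  keep <- !(mon == 2L & day == 29L)
  raw <- raw[keep, , drop = FALSE]
  mon <- mon[keep]; day <- day[keep]; d <- d[keep]
  df <- data.frame(year = as.integer(format(d, "%Y")), month = mon, day = day,
                   doy = doy_of(mon, day),
                   tmax = as.numeric(raw$tmax), tmin = as.numeric(raw$tmin),
                   precip = as.numeric(raw$precip))
  if ("sun_hours" %in% names(raw)) df$sun_hours <- as.numeric(raw$sun_hours)
  if ("radiation" %in% names(raw)) df$radiation <- as.numeric(raw$radiation)
  weather_series(df, site, validate = FALSE)
}

#' Write a weather series to CSV
#'
#' Inverse of [read_weather_csv()]; synthetic years are written as calendar
#' years starting at `base_year` so dates stay ISO-8601.
#'
#' @param x weather_series.
#' @param path output file.
#' @param base_year calendar year assigned to simulated year 1.
#' @export
write_weather_csv <- function(x, path, base_year = 2001L) {
  date <- sprintf("%04d-%02d-%02d", base_year - min(x$year) + x$year,
                  x$month, x$day)
  out <- data.frame(date = date, tmax = x$tmax, tmin = x$tmin,
                    precip = x$precip)
  if ("sun_hours" %in% names(x)) out$sun_hours <- x$sun_hours
  if ("radiation" %in% names(x)) out$radiation <- x$radiation
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default quality-control thresholds
#'
#' Magnitude gates for screening station records before fitting the
#' generator; values outside them are treated as erroneous, removed and
#' gap-filled climatologically.
#'
#' @param tmax_range,tmin_range plausible bounds (deg C).
#' @param precip_max maximum credible daily total (mm).
#' @param max_missing maximum tolerated missing/flagged fraction for
#'   temperature or precipitation before the site is rejected.
#' @return list of rules for [qc_series()].
#' @export
qc_rules <- function(tmax_range = c(-30, 45), tmin_range = c(-35, 40),
                     precip_max = 300, max_missing = 0.10) {
  list(tmax_range = tmax_range, tmin_range = tmin_range,
       precip_max = precip_max, max_missing = max_missing)
}

#' Quality-control a daily weather series
#'
#' Flags physically impossible or implausible values (tmax < tmin, negative
#' or extreme precipitation, out-of-range temperatures, missing entries),
#' replaces them by calendar-day climatological means computed from the
#' remaining years, and attaches a report with the fraction removed per
#' variable. Sites whose temperature or precipitation record is more than
#' `max_missing` flagged/missing are rejected with an error, mirroring the
#' usual station-selection rule.
#'
#' @param raw weather_series (possibly with NAs).
#' @param rules output of [qc_rules()].
#' @return clean `weather_series` with a `qc` attribute; retrieve the report
#'   with [qc_report()].
#' @export
qc_series <- function(raw, rules = qc_rules()) {
  df <- as.data.frame(raw)
  n <- nrow(df)
  flag <- list(
    tmax = is.na(df$tmax) | df$tmax < rules$tmax_range[1] |
      df$tmax > rules$tmax_range[2],
    tmin = is.na(df$tmin) | df$tmin < rules$tmin_range[1] |
      df$tmin > rules$tmin_range[2],
    precip = is.na(df$precip) | df$precip < 0 | df$precip > rules$precip_max
  )
  inverted <- !flag$tmax & !flag$tmin & df$tmax < df$tmin
  flag$tmax <- flag$tmax | inverted
  flag$tmin <- flag$tmin | inverted
  frac <- vapply(flag, mean, numeric(1))
  if (max(frac[c("tmax", "tmin", "precip")]) > rules$max_missing)
    stop(sprintf(
      "site rejected: %.1f%% of %s flagged or missing (limit %.0f%%)",
      100 * max(frac), names(which.max(frac)), 100 * rules$max_missing))
  for (v in names(flag)) {
    bad <- flag[[v]]
    if (!any(bad)) next
    ok_val <- ifelse(bad, NA_real_, df[[v]])
    clim <- tapply(ok_val, df$doy, mean, na.rm = TRUE)
    fill <- as.numeric(clim[as.character(df$doy[bad])])
    # calendar days never observed clean: fall back to linear interpolation
    if (anyNA(fill)) {
      idx <- seq_len(n)
      interp <- stats::approx(idx[!bad], df[[v]][!bad], xout = idx[bad],
                              rule = 2)$y
      fill[is.na(fill)] <- interp[is.na(fill)]
    }
    df[[v]][bad] <- fill
  }
  # residual inversions after independent gap-fill
  inv2 <- df$tmax < df$tmin
  if (any(inv2)) {
    mid <- (df$tmax[inv2] + df$tmin[inv2]) / 2
    df$tmax[inv2] <- mid + 0.5
    df$tmin[inv2] <- mid - 0.5
  }
  if ("sun_hours" %in% names(df)) {
    N <- daylength(series_site(raw)$latitude, df$doy)
    df$sun_hours[is.na(df$sun_hours)] <- 0
    df$sun_hours <- pmin(pmax(df$sun_hours, 0), N)
  }
  report <- list(n_days = n, n_flagged = vapply(flag, sum, integer(1)),
                 fraction_flagged = frac)
  out <- weather_series(df, series_site(raw), seed = attr(raw, "seed"))
  attr(out, "qc") <- report
  out
}

#' Quality-control report of a cleaned series
#' @param x result of [qc_series()].
#' @return list with `n_days`, `n_flagged`, `fraction_flagged`.
#' @export
qc_report <- function(x) attr(x, "qc")
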