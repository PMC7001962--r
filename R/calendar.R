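# 365-day simulation calendar: every simulated year is structurally identical
# (29 Feb dropped on import), so multi-year day counting needs no leap logic.

MONTH_LENGTHS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
MONTH_STARTS <- c(0L, cumsum(MONTH_LENGTHS))[1:12] + 1L
DAYS_PER_YEAR <- 365L

#' Calendar month for each day of a 365-day year
#'
#' @param doy Integer day of year, 1--365.
#' @return Integer month 1--12.
#' @export
month_of_doy <- function(doy) {
  stopifnot(all(doy >= 1L), all(doy <= DAYS_PER_YEAR))
  findInterval(doy, MONTH_STARTS)
}

#' Day of year for a month/day pair (365-day calendar)
#'
#' @param month Integer month 1--12.
#' @param day Integer day of month.
#' @return Integer day of year.
#' @export
doy_of <- function(month, day) {
  stopifnot(all(month >= 1L), all(month <= 12L),
            all(day >= 1L), all(day <= MONTH_LENGTHS[month]))
  MONTH_STARTS[month] + as.integer(day) - 1L
}

# Default sowing date for UK winter wheat: 20 October.
SOWING_DOY_DEFAULT <- 293L  # doy_of(10, 20)

# month index for every day of one year, recycled over multi-year series
month_index_365 <- function(n_years = 1L) {
  rep(rep.int(1:12, MONTH_LENGTHS), times = n_years)
}

doy_index_365 <- function(n_years = 1L) {
  rep.int(seq_len(DAYS_PER_YEAR), n_years)
}
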