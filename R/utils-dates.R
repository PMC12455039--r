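# Calendar arithmetic helpers shared by the trial grid and eligibility code.
# Months are added on the calendar (day-of-month clamped to the target month),
# so attained-age dates use exact day arithmetic from the birth date.

days_in_month <- function(year, month) {
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  d <- base[month]
  leap <- (year %% 4L == 0L & year %% 100L != 0L) | (year %% 400L == 0L)
  d[month == 2L & leap] <- 29L
  d
}

#' Add whole months to dates
#'
#' Vectorised calendar month addition; the day of month is clamped to the
#' length of the target month (e.g. 31 Jan + 1 month = 28/29 Feb).
#'
#' @param dates a `Date` vector.
#' @param months integer vector of months to add (recycled).
#' @return a `Date` vector.
#' @keywords internal
add_months <- function(dates, months) {
  lt <- as.POSIXlt(dates)
  total <- lt$year * 12L + lt$mon + as.integer(months)
  yr <- total %/% 12L + 1900L
  mo <- total %% 12L + 1L
  day <- pmin(lt$mday, days_in_month(yr, mo))
  as.Date(sprintf("%04d-%02d-%02d", yr, mo, day))
}

# First day of the month containing each date.
floor_month <- function(dates) {
  lt <- as.POSIXlt(dates)
  as.Date(sprintf("%04d-%02d-01", lt$year + 1900L, lt$mon + 1L))
}

# Exact age in years at `at` for someone born on `birth` (fractional).
age_years_at <- function(birth, at) {
  as.numeric(at - birth) / 365.25
}
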