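#' Sequential trial grid
#'
#' Builds the ordered list of trial time points for the sequential design.
#' On the age axis, points start at `start` years and advance in
#' `step_months` steps while remaining below the `end + 1` year boundary, so
#' an inclusive-year window of ages 50-84 with 3-month steps yields
#' 4 x 35 = 140 trials (index ages 50.00, 50.25, ..., 84.75). On the
#' calendar axis, points run at `step_months` steps from the first day of
#' the start month through the last step beginning within the end month
#' (January 2000 to December 2020 yields 84 quarterly trials).
#'
#' @param axis `"age"` or `"calendar"`.
#' @param start,end age in whole years (age axis) or `Date`/`"YYYY-MM"`
#'   strings (calendar axis); `start` must precede `end`.
#' @param step_months spacing of consecutive trials in months (default 3).
#' @return an object of class `trial_grid` with elements `axis`,
#'   `step_months` and `points` (age in months for the age axis, `Date`
#'   index dates for the calendar axis); `length()` gives the trial count.
#' @examples
#' length(trial_grid("age", 50, 84))         # 140
#' length(trial_grid("calendar", "2000-01", "2020-12"))  # 84
#' @export
trial_grid <- function(axis = c("age", "calendar"), start, end, step_months = 3L) {
  axis <- match.arg(axis)
  step_months <- as.integer(step_months)
  if (step_months < 1L) stop("step_months must be >= 1")
  if (axis == "age") {
    if (!(is.numeric(start) && is.numeric(end))) stop("ages must be numeric years")
    if (end < start) stop("end age precedes start age")
    from <- as.integer(round(12 * start))
    upper <- as.integer(12 * (end + 1))  # exclusive boundary of the last year
    points <- seq.int(from, upper - 1L, by = step_months)
  } else {
    start <- parse_month(start)
    end <- parse_month(end)
    if (end < start) stop("end month precedes start month")
    n_mo <- month_diff(start, end)
    points <- add_months(start, seq.int(0L, n_mo, by = step_months))
  }
  structure(list(axis = axis, step_months = step_months, points = points),
            class = "trial_grid")
}

#' @export
length.trial_grid <- function(x) length(x$points)

#' @export
print.trial_grid <- function(x, ...) {
  cat("<trial_grid>", length(x$points), "trials on the", x$axis,
      "axis, every", x$step_months, "months\n")
  invisible(x)
}

parse_month <- function(x) {
  if (inherits(x, "Date")) return(floor_month(x))
  if (is.character(x) && grepl("^\\d{4}-\\d{2}$", x))
    return(as.Date(paste0(x, "-01")))
  floor_month(as.Date(x))
}

month_diff <- function(a, b) {
  la <- as.POSIXlt(a); lb <- as.POSIXlt(b)
  (lb$year - la$year) * 12L + (lb$mon - la$mon)
}

#' Resolve a trial point to per-patient index dates
#'
#' Age-axis points resolve to the exact calendar date each patient attains
#' that age (whole months added to the birth date); calendar-axis points are
#' the same date for everyone.
#'
#' @param grid a [trial_grid()].
#' @param trial index of the trial within the grid.
#' @param birth_dates `Date` vector of birth dates.
#' @return `Date` vector of index dates, one per patient.
#' @export
index_dates_for <- function(grid, trial, birth_dates) {
  pt <- grid$points[trial]
  if (grid$axis == "age") add_months(birth_dates, pt)
  else rep(pt, length(birth_dates))
}
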