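#' Assign timestamps to activity days
#'
#' City-level calling activity is nearly null around 04:00, so the analysis
#' day runs from 04:00 of a calendar day to 03:59 of the next. A timestamp
#' is mapped to the day index `d` of the calendar day containing its 04:00
#' boundary and an *extended hour* in `[4, 28)`: hours 24--28 encode
#' 00:00--03:59 of the following calendar day.
#'
#' @param ts POSIXct vector (civil clock time) within the study year. The
#'   study runs from `year` Jan 1 04:00 to `year + 1` Jan 1 03:59 (the tail
#'   of the last activity day); timestamps outside that span, including the
#'   un-assignable opening gap `[Jan 1 00:00, Jan 1 04:00)`, raise an error.
#' @param year Study year.
#' @return A `data.table` with columns `day` (1..365) and `extended_hour`.
#' @examples
#' ts <- as.POSIXct("2007-08-02 03:30:00", tz = "UTC")
#' assign_activity_day(ts)  # day of Aug 1, extended_hour 27.5
#' @export
assign_activity_day <- function(ts, year = 2007) {
  lt <- as.POSIXlt(ts, tz = "UTC")
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  yr <- lt$year + 1900
  next_tail <- yr == year + 1 & lt$yday == 0 & hour < 4
  if (any(yr != year & !next_tail))
    stop("timestamp outside the study year ", year)
  before4 <- hour < 4
  d <- ifelse(next_tail, .days_in_year(year), lt$yday + 1 - before4)
  if (any(d < 1))
    stop("timestamps in [Jan 1 00:00, Jan 1 04:00) belong to the previous ",
         "year's last activity day and are outside the study")
  data.table::data.table(day = d, extended_hour = hour + 24 * before4)
}

.days_in_year <- function(year) {
  as.integer(as.Date(sprintf("%d-12-31", year)) -
               as.Date(sprintf("%d-01-01", year))) + 1L
}

# windows (extended hours): morning [5,16), night [17,28); each 11 h long
.MORNING_WINDOW <- c(5, 16)
.NIGHT_WINDOW <- c(17, 28)

.first_last_calls <- function(calls, window, which = c("first", "last")) {
  which <- match.arg(which)
  calls <- data.table::as.data.table(calls)
  stopifnot(all(c("caller_id", "day", "extended_hour") %in% names(calls)))
  win <- calls[extended_hour >= window[1] & extended_hour < window[2]]
  f <- if (which == "first") min else max
  by_cols <- intersect(c("city", "caller_id", "day"), names(win))
  out <- win[, .(time = f(extended_hour)), by = by_cols]
  data.table::setorderv(out, by_cols)
  out[]
}

#' Per-user first and last call times
#'
#' `extract_first_calls()` keeps, for each user and activity day, the
#' earliest call in the morning window `[5, 16)` extended hours;
#' `extract_last_calls()` keeps the latest call in the night window
#' `[17, 28)`. Users with no call in the window on that day are omitted.
#' Both windows are 11 h long and calls between 04:00 and 05:00 or between
#' 16:00 and 17:00 enter neither.
#'
#' @param calls A data.frame with columns `caller_id`, `day`,
#'   `extended_hour` (and optionally `city`, preserved in the grouping).
#' @return A `data.table` with one row per (city,) user and day: `time` in
#'   extended hours.
#' @export
extract_first_calls <- function(calls) {
  .first_last_calls(calls, .MORNING_WINDOW, "first")
}

#' @rdname extract_first_calls
#' @export
extract_last_calls <- function(calls) {
  .first_last_calls(calls, .NIGHT_WINDOW, "last")
}

#' Binned time-of-day distribution
#'
#' Normalized histogram of event times over a half-open window in extended
#' hours; the concrete form of the calling-activity distributions
#' (all-call, first-call and last-call). The default 5-minute bin equals
#' the alignment grid step, so candidate shifts are whole-bin moves.
#'
#' @param times Numeric vector of extended hours, all inside `window`.
#' @param window `c(start, end)` in extended hours; `end - start` must be
#'   a multiple of the bin width.
#' @param bin_width Bin width in minutes (default 5).
#' @return An object of class `binned_distribution`: list with `window`,
#'   `bin_width` (minutes), `breaks`, `centers`, `probs`, `n_events`.
#'   With no events, `probs` is all zero and `n_events = 0`.
#' @export
binned_distribution <- function(times, window = .NIGHT_WINDOW,
                                bin_width = 5) {
  wh <- bin_width / 60
  nb <- (window[2] - window[1]) / wh
  if (abs(nb - round(nb)) > 1e-9)
    stop("window length must be a whole number of bins")
  nb <- round(nb)
  breaks <- window[1] + (0:nb) * wh
  if (length(times) && (any(times < window[1]) || any(times >= window[2])))
    stop("all times must lie inside the window [",
         window[1], ", ", window[2], ")")
  idx <- pmin(nb, floor((times - window[1]) / wh) + 1)
  counts <- tabulate(idx, nbins = nb)
  n <- length(times)
  structure(list(window = window, bin_width = bin_width, breaks = breaks,
                 centers = breaks[-length(breaks)] + wh / 2,
                 probs = if (n > 0) counts / n else numeric(nb),
                 n_events = n),
            class = "binned_distribution")
}

#' @export
print.binned_distribution <- function(x, ...) {
  cat(sprintf(
    "<binned_distribution> window [%g, %g) h, %g-min bins, %d events\n",
    x$window[1], x$window[2], x$bin_width, x$n_events))
  invisible(x)
}

#' Mean time of a binned distribution
#'
#' Probability-weighted mean of the bin centres, in extended hours.
#'
#' @param dist A [binned_distribution()] with at least one event.
#' @return Extended hours inside the window.
#' @export
mean_time <- function(dist) {
  stopifnot(inherits(dist, "binned_distribution"))
  if (dist$n_events == 0)
    stop("mean time is undefined for an empty distribution")
  sum(dist$probs * dist$centers)
}

#' Per-city daily timing series
#'
#' For each (city, day), the mean first-call time `t_F` (raw-time mean over
#' the users' morning first calls) and mean last-call time `t_L` (night
#' last calls), plus the contributing user counts. The raw-time mean is
#' used rather than the binned mean; at 5-minute bins the two are
#' indistinguishable.
#'
#' @param calls Data.frame with `city`, `caller_id`, `day`,
#'   `extended_hour`.
#' @param year Study year, used to label weekdays.
#' @return A `data.table` `city, day, weekday, t_F, t_L, n_users_F,
#'   n_users_L`; `t_F`/`t_L` are `NA` where a window had no callers.
#' @export
daily_timing_series <- function(calls, year = 2007) {
  fc <- extract_first_calls(calls)[, .(t_F = mean(time), n_users_F = .N),
                                   by = .(city, day)]
  lc <- extract_last_calls(calls)[, .(t_L = mean(time), n_users_L = .N),
                                  by = .(city, day)]
  out <- merge(fc, lc, by = c("city", "day"), all = TRUE)
  out[, weekday := day_of_week(day, year)]
  data.table::setcolorder(out, c("city", "day", "weekday", "t_F", "t_L",
                                 "n_users_F", "n_users_L"))
  data.table::setorder(out, city, day)
  out[]
}
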