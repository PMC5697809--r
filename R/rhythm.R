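#' Collapse a band's timing series onto the reference meridian
#'
#' Cities further west experience every solar event later; before averaging
#' across a latitudinal band, each city's mean first/last-call times are
#' advanced by its sun-transit delay relative to the reference city
#' ([transit_delay()]), so that solar-entrained cities coincide after the
#' shift.
#'
#' @param series A [daily_timing_series()] table (`city, day, t_F, t_L,
#'   ...`).
#' @param cities City registry rows with `id`, `rel_longitude`.
#' @param reference_id The band's reference city id.
#' @return The series with `t_F`, `t_L` replaced by their shifted values;
#'   cities without a registered longitude are dropped.
#' @export
collapse_band <- function(series, cities, reference_id) {
  series <- data.table::copy(data.table::as.data.table(series))
  cities <- data.table::as.data.table(cities)
  ref_lon <- cities[id == reference_id, rel_longitude]
  if (!length(ref_lon)) stop("reference city not found")
  m <- match(series$city, cities$id)
  known <- !is.na(m) & !is.na(cities$rel_longitude[m])
  series <- series[known]
  delay_h <- transit_delay(cities$rel_longitude[m[known]], ref_lon) / 60
  series[, `:=`(t_F = t_F - delay_h, t_L = t_L - delay_h)]
  series[]
}

#' Band-average timing series
#'
#' Unweighted arithmetic mean of the (collapsed) per-city mean first- and
#' last-call times across the cities of a band, per day.
#'
#' @param collapsed Output of [collapse_band()].
#' @return A `data.table` `day, tF_bar, tL_bar, n_cities`.
#' @export
band_average <- function(collapsed) {
  collapsed <- data.table::as.data.table(collapsed)
  out <- collapsed[, .(tF_bar = mean(t_F, na.rm = TRUE),
                       tL_bar = mean(t_L, na.rm = TRUE),
                       n_cities = .N), by = day]
  data.table::setorder(out, day)
  out[]
}

#' Remove holiday days from a timing series
#'
#' National holidays and local festivities disrupt the regular calling
#' pattern and are excluded from the annual curves. No calendar is built
#' in (the study country is masked); supply the day indices.
#'
#' @param series Data.frame with a `day` column.
#' @param holiday_days Integer day indices to drop.
#' @return The filtered table; the number removed is in
#'   `attr(, "n_removed")`.
#' @export
filter_holidays <- function(series, holiday_days = integer()) {
  series <- data.table::as.data.table(series)
  out <- series[!day %in% holiday_days]
  data.table::setattr(out, "n_removed", nrow(series) - nrow(out))
  out[]
}

#' Period of low calling activity
#'
#' Elapsed time from the mean last-call time of day `d` to the mean
#' first-call time of day `d + 1`:
#' `T_LCA = (t_F + 24) - t_L`.
#'
#' @param t_L Mean last-call time in extended hours of day `d`
#'   (`[17, 28)`; values past civil midnight exceed 24).
#' @param t_F_next Mean first-call time of day `d + 1` (`[5, 16)`).
#' @return Hours, strictly positive.
#' @examples
#' low_activity_period(23, 8)    # 9 h
#' low_activity_period(25, 7)    # last call 01:00 -> 6 h
#' @export
low_activity_period <- function(t_L, t_F_next) {
  out <- (t_F_next + 24) - t_L
  if (any(out <= 0, na.rm = TRUE))
    stop("non-positive low-activity period: t_L/t_F are inconsistent")
  out
}

#' Population mid-sleep time
#'
#' Midpoint of the low-activity interval, interpreted as the population's
#' mid-sleep time: `t_mid = (t_L + t_F - 24) / 2`, with `t_L` on the
#' extended (0--24+) clock of day `d` so the formula needs no
#' case-splitting for last calls past civil midnight.
#'
#' @inheritParams low_activity_period
#' @return Clock hours in `[0, 24)`, typically 2--5 (small hours).
#' @examples
#' mid_sleep(23, 8)     # 03:30
#' mid_sleep(24.5, 8)   # last call 00:30 -> 04:15
#' @export
mid_sleep <- function(t_L, t_F_next) {
  ((t_L + t_F_next - 24) / 2) %% 24
}

#' Cohort-resolved timing metrics
#'
#' Pools each (age-bin, gender, weekday) cohort's first- and last-call
#' times across the study period and derives the cohort's mean timings,
#' low-activity period and mid-sleep time. A row labelled by weekday `w`
#' spans the night of `w` (last calls) and the following morning (first
#' calls of the next activity day), so a "Saturday" row describes the
#' Saturday-night-to-Sunday-morning rest period.
#'
#' @param calls Data.frame `caller_id, day, extended_hour` (a `city`
#'   column, if present, adds a grouping level).
#' @param subscribers Demographics with `id`, `age`, `gender`.
#' @param age_breaks Left-closed break points of the age bins; default
#'   2-year bins spanning ages 18--80.
#' @param min_users Cohorts whose morning or night pool draws on fewer
#'   distinct users are suppressed (default 50).
#' @param pool_mon_thu Pool Monday--Thursday into one `"Mon-Thu"` level
#'   (their timings are near-identical); default FALSE.
#' @param year Study year.
#' @return A `data.table` `(city,) age_lo, age_hi, gender, weekday, t_F,
#'   t_L, T_LCA, t_mid, n_users`.
#' @export
cohort_metrics <- function(calls, subscribers,
                           age_breaks = seq(18, 80, by = 2),
                           min_users = 50, pool_mon_thu = FALSE,
                           year = 2007) {
  calls <- data.table::as.data.table(calls)
  subs <- data.table::as.data.table(subscribers)
  fc <- extract_first_calls(calls)
  lc <- extract_last_calls(calls)
  # mornings are labelled by the weekday of the *preceding* night's day
  annotate <- function(ev, day_shift = 0) {
    ev <- merge(ev, subs[, .(caller_id = id, age, gender)],
                by = "caller_id")
    ev <- ev[age >= age_breaks[1] & age <= age_breaks[length(age_breaks)]]
    bin <- findInterval(ev$age, age_breaks, rightmost.closed = TRUE)
    ev[, `:=`(age_lo = age_breaks[bin],
              age_hi = age_breaks[pmin(bin + 1, length(age_breaks))])]
    ev[, weekday := as.character(day_of_week(day - day_shift, year))]
    if (pool_mon_thu)
      ev[weekday %in% c("Mon", "Tue", "Wed", "Thu"), weekday := "Mon-Thu"]
    ev
  }
  by_cols <- c(intersect("city", names(calls)),
               "age_lo", "age_hi", "gender", "weekday")
  agg <- function(ev, col) {
    out <- ev[, list(.val = mean(time),
                     .n = data.table::uniqueN(caller_id)), by = by_cols]
    data.table::setnames(out, c(".val", ".n"), c(col, paste0("n_", col)))
    out
  }
  out <- merge(agg(annotate(fc, day_shift = 1), "t_F"),
               agg(annotate(lc, day_shift = 0), "t_L"),
               by = by_cols)
  out <- out[n_t_F >= min_users & n_t_L >= min_users]
  out[, `:=`(T_LCA = low_activity_period(t_L, t_F),
             t_mid = mid_sleep(t_L, t_F),
             n_users = pmin(n_t_F, n_t_L))]
  out[, c("n_t_F", "n_t_L") := NULL]
  wk_levels <- if (pool_mon_thu) c("Mon-Thu", "Fri", "Sat", "Sun") else
    .WEEKDAYS
  out[, weekday := factor(weekday, levels = wk_levels)]
  data.table::setorderv(out, by_cols)
  out[]
}

#' Calling-activity timings versus solar cues
#'
#' Aligns a band's daily averaged timing curves with the solar-midnight
#' and sunrise curves of the band's reference location, all in zone clock
#' time, one row per day. Interior extremum days of each curve are
#' annotated so the seasonal turning points can be compared.
#'
#' @param band_series Output of [band_average()] (columns `day, tF_bar,
#'   tL_bar`).
#' @param lat Band latitude in degrees.
#' @param lon Reference relative longitude (degrees).
#' @param rules A [clock_rules()].
#' @return A `data.table` `day, tF_bar, tL_bar, solar_midnight, sunrise`
#'   with an `extrema` attribute: a data.frame `curve, day, type` of
#'   interior extrema (DST changeover days excluded for the solar curves).
#' @export
solar_comparison_report <- function(band_series, lat, lon,
                                    rules = clock_rules()) {
  bs <- data.table::as.data.table(band_series)
  days <- bs$day
  rs <- sunrise_sunset(lat, lon, days, rules)
  out <- data.table::data.table(
    day = days, tF_bar = bs$tF_bar, tL_bar = bs$tL_bar,
    solar_midnight = solar_midnight(lat, lon, days, rules),
    sunrise = rs$sunrise)
  sm_ext <- solar_midnight_extrema(lat, lon, rules)
  interior_extrema <- function(curve, v, d) {
    lo <- integer(); hi <- integer()
    if (length(v) >= 3) {
      i <- 2:(length(v) - 1)
      lo <- i[v[i] < v[i - 1] & v[i] < v[i + 1]]
      hi <- i[v[i] > v[i - 1] & v[i] > v[i + 1]]
    }
    data.frame(curve = rep(curve, length(lo) + length(hi)),
               day = c(d[lo], d[hi]),
               type = c(rep("min", length(lo)), rep("max", length(hi))))
  }
  ext <- rbind(
    interior_extrema("tF_bar", out$tF_bar, days),
    interior_extrema("tL_bar", out$tL_bar, days),
    data.frame(curve = rep("solar_midnight", nrow(sm_ext)),
               day = sm_ext$day, type = sm_ext$type))
  data.table::setattr(out, "extrema", ext)
  out[]
}
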