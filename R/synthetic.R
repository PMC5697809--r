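#' Configuration for the synthetic CDR generator
#'
#' Defines a synthetic study population whose calling activity has the
#' statistical structure the analysis pipeline assumes: a bimodal daily
#' intensity (morning peak near noon, evening peak near 20:00, afternoon
#' trough near 16:00, near-null activity around 04:00), a per-city phase
#' equal to the city's sun-transit delay (4 min per degree of longitude),
#' a seasonal phase term coupled to the solar-midnight deviation, weekday
#' offsets, and per-cohort mid-sleep offsets. Every injected parameter is
#' recorded in a ground-truth sidecar so recovery tests cannot cheat.
#'
#' The default city set is a single latitudinal band at 42 N with five
#' cities at relative longitudes -7.8, -4.7, -3.7, 0 and +3 degrees
#' (transit delays +31.2, +18.8, +14.8, 0 and -12 minutes); the default
#' cohorts inject a 30-minute young-versus-old mid-sleep gap and a
#' 12-minute female-versus-male gap.
#'
#' @param seed Master RNG seed; per-(city, day, cohort) substreams are
#'   derived from it so generation is reproducible.
#' @param year Study year (weekday labels, timestamps).
#' @param cities Data.frame in the [read_cities()] layout.
#' @param users_per_city Subscribers per city.
#' @param cohorts Data.frame `age_lo, age_hi, gender, fraction,
#'   t_mid_offset_min`; fractions must sum to 1.
#' @param morning_peak,evening_peak Lists `center` (extended hours), `sd`
#'   (hours), `weight` of the two intensity bumps.
#' @param trough_floor Baseline calling rate as a fraction of the bump
#'   peak rate (default 0.01: near-null overnight activity).
#' @param seasonal_amplitude Dimensionless coupling in [0, 1] of the phase
#'   to the solar-midnight deviation from its annual mean.
#' @param weekday_offsets_min Named vector Mon..Sun of phase offsets in
#'   minutes (later nights on Fridays/Saturdays by default).
#' @param calls_per_user_day Mean number of outgoing calls per user-day.
#' @param rules [clock_rules()] used for the seasonal solar term.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(
    seed = 1L, year = 2007,
    cities = default_band_cities(),
    users_per_city = 1000L,
    cohorts = default_cohorts(),
    morning_peak = list(center = 12, sd = 1.3, weight = 0.45),
    evening_peak = list(center = 20, sd = 1.5, weight = 0.55),
    trough_floor = 0.01,
    seasonal_amplitude = 0.3,
    weekday_offsets_min = c(Mon = 0, Tue = 0, Wed = 0, Thu = 0,
                            Fri = 30, Sat = 45, Sun = 0),
    calls_per_user_day = 3,
    rules = clock_rules()) {
  cohorts <- data.table::as.data.table(cohorts)
  if (abs(sum(cohorts$fraction) - 1) > 1e-8)
    stop("cohort fractions must sum to 1")
  if (morning_peak$weight <= 0 || evening_peak$weight <= 0)
    stop("peak weights must be positive")
  if (seasonal_amplitude < 0 || seasonal_amplitude > 1)
    stop("seasonal_amplitude must lie in [0, 1]")
  if (!all(.WEEKDAYS %in% names(weekday_offsets_min)))
    stop("weekday_offsets_min must be named Mon..Sun")
  cfg <- list(seed = as.integer(seed), year = year,
              cities = data.table::as.data.table(cities),
              users_per_city = as.integer(users_per_city),
              cohorts = cohorts,
              morning_peak = morning_peak, evening_peak = evening_peak,
              trough_floor = trough_floor,
              seasonal_amplitude = seasonal_amplitude,
              weekday_offsets_min = weekday_offsets_min,
              calls_per_user_day = calls_per_user_day,
              rules = rules)
  # seasonal phase term (hours): solar-midnight deviation at the band
  # reference meridian, scaled by the coupling amplitude
  lat0 <- mean(cfg$cities$band_latitude)
  sm <- solar_midnight(lat0, 0, 1:365, rules)
  cfg$seasonal_phase_h <- seasonal_amplitude * (sm - mean(sm))
  structure(cfg, class = "generator_config")
}

#' @rdname generator_config
#' @export
default_band_cities <- function() {
  data.table::data.table(
    id = c("west1", "west2", "west3", "ref", "east1"),
    band_latitude = 42, band_halfwidth = 40 / 60,
    rel_longitude = c(-7.8, -4.7, -3.7, 0, 3.0),
    population = c(500000L, 300000L, 200000L, 400000L, 150000L),
    center_lat = 42, center_lon = c(-7.8, -4.7, -3.7, 0, 3.0))
}

#' @rdname generator_config
#' @export
default_cohorts <- function() {
  base <- data.table::data.table(
    age_lo = c(20, 40, 70), age_hi = c(30, 50, 80),
    age_offset = c(30, 10, 0))
  out <- data.table::rbindlist(lapply(c("female", "male"), function(g) {
    b <- data.table::copy(base)
    b[, `:=`(gender = g,
             t_mid_offset_min = age_offset + ifelse(g == "female", 12, 0))]
    b
  }))
  out[, `:=`(fraction = 1 / .N, age_offset = NULL)]
  out[]
}

#' Daily calling-intensity function
#'
#' Builds the inhomogeneous Poisson intensity `lambda(t)` (calls per hour,
#' extended hours `t` in [4, 28)) for one city, cohort and day: a constant
#' floor plus two truncated-Gaussian bumps (renormalized on the window),
#' all centres shifted by the city's transit delay, the seasonal
#' solar-midnight term, the weekday offset and the cohort offset. The
#' closed-form integral is attached for test oracles.
#'
#' @param config A [generator_config()].
#' @param city One row of `config$cities` (needs `rel_longitude`).
#' @param cohort One row of `config$cohorts` (needs `t_mid_offset_min`);
#'   pass `NULL` for a zero cohort offset.
#' @param d Day-of-year index.
#' @return A function `lambda(t)`, with attributes `phase_h`, `integral`
#'   (expected calls per user-day), `max_rate` and `centers`.
#' @export
daily_intensity <- function(config, city, cohort, d) {
  stopifnot(inherits(config, "generator_config"))
  wd <- as.character(day_of_week(d, config$year))
  phase_h <- transit_delay(city$rel_longitude, 0) / 60 +
    config$seasonal_phase_h[d] +
    config$weekday_offsets_min[[wd]] / 60 +
    (if (is.null(cohort)) 0 else cohort$t_mid_offset_min / 60)
  peaks <- list(config$morning_peak, config$evening_peak)
  centers <- vapply(peaks, function(p) p$center + phase_h, numeric(1))
  sds <- vapply(peaks, `[[`, numeric(1), "sd")
  ws <- vapply(peaks, `[[`, numeric(1), "weight")
  # truncation renormalizers so each bump carries exactly its weight
  zs <- pnorm(28, centers, sds) - pnorm(4, centers, sds)
  bump <- function(t) {
    s <- 0
    for (i in seq_along(ws)) s <- s + ws[i] * dnorm(t, centers[i], sds[i]) / zs[i]
    s
  }
  peak_rate <- max(bump(seq(4, 28, by = 0.01)))
  floor_rate <- config$trough_floor * peak_rate
  # scale so the expected number of calls per user-day is as configured
  k <- config$calls_per_user_day / (sum(ws) + floor_rate * 24)
  lam <- function(t) k * (bump(t) + floor_rate)
  attr(lam, "phase_h") <- phase_h
  attr(lam, "integral") <- config$calls_per_user_day
  attr(lam, "max_rate") <- k * (peak_rate + floor_rate)
  attr(lam, "centers") <- centers
  lam
}

#' Sample call times from an intensity function
#'
#' Inhomogeneous Poisson sampling by thinning against the intensity's
#' maximum rate. Uses the current RNG state; seed it (or use
#' [generate_dataset()], which derives one substream per city-day block)
#' for reproducibility.
#'
#' @param lambda An intensity from [daily_intensity()] (any non-negative
#'   function with a `max_rate` attribute works).
#' @param n_users Number of independent user-days to draw.
#' @return A `data.table` `user` (index 1..n_users), `t` (extended
#'   hours), sorted by user then time; users without calls are absent.
#' @export
sample_calls <- function(lambda, n_users = 1L) {
  M <- attr(lambda, "max_rate")
  if (is.null(M)) M <- max(lambda(seq(4, 28, by = 0.01)))
  if (M <= 0) return(data.table::data.table(user = integer(), t = numeric()))
  n_prop <- rpois(n_users, M * 24)
  total <- sum(n_prop)
  if (total == 0) return(data.table::data.table(user = integer(), t = numeric()))
  t <- runif(total, 4, 28)
  keep <- runif(total) < lambda(t) / M
  out <- data.table::data.table(user = rep(seq_len(n_users), n_prop)[keep],
                                t = t[keep])
  data.table::setorder(out, user, t)
  out[]
}

# deterministic substream seed per (city, day, cohort), < 2^31
.block_seed <- function(seed, ci, d, coh) {
  (((seed %% 65536) * 7919 + ci * 104729) %% 2147483647 * 131 +
     d * 1009 + coh) %% 2147483647
}

#' Generate a synthetic CDR dataset
#'
#' Draws call events for every (city, day, cohort) block from the
#' configured intensity via Poisson thinning, builds the matching
#' subscriber demographics (coordinates placed inside the residence rules)
#' and city registry, and records all injected parameters in a truth
#' sidecar. With `dir` given, writes `cdr.csv`, `subscribers.csv`,
#' `cities.csv`, `truth_cities.csv` and `truth_cohorts.csv` in the
#' [read_cdr()]/[read_subscribers()]/[read_cities()] layouts.
#'
#' @param config A [generator_config()].
#' @param days Day-of-year indices to simulate (default 1..56, eight
#'   weeks).
#' @param dir Optional output directory (created if missing).
#' @return Invisibly, a list with `records` (CDR table as from
#'   [read_cdr()]), `subscribers`, `cities`, `truth` (list `cities`,
#'   `cohorts`, `seasonal_amplitude`) and, if written, `paths`.
#' @export
generate_dataset <- function(config, days = 1:56, dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  cities <- config$cities
  cohorts <- config$cohorts
  n_u <- config$users_per_city

  # subscribers: deterministic cohort allocation, coordinates near centre
  subs <- list()
  for (ci in seq_len(nrow(cities))) {
    city <- cities[ci]
    n_coh <- .allocate(n_u, cohorts$fraction)
    set.seed(.block_seed(config$seed, ci, 0L, 0L))
    coh_idx <- rep(seq_len(nrow(cohorts)), n_coh)
    if (n_u > 0) {
      age <- floor(runif(n_u, cohorts$age_lo[coh_idx],
                         cohorts$age_hi[coh_idx]))
      jitter <- function(km) rnorm(n_u, 0, km / 111)
      subs[[ci]] <- data.table::data.table(
        id = sprintf("%s_u%05d", city$id, seq_len(n_u)),
        age = age, gender = cohorts$gender[coh_idx],
        postal_lat = city$center_lat + jitter(3),
        postal_lon = city$center_lon + jitter(3),
        tower_lat = city$center_lat + jitter(3),
        tower_lon = city$center_lon + jitter(3),
        home_city = city$id, cohort = coh_idx)
    }
  }
  proto <- data.table::data.table(
    id = character(), age = numeric(), gender = character(),
    postal_lat = numeric(), postal_lon = numeric(),
    tower_lat = numeric(), tower_lon = numeric(),
    home_city = character(), cohort = integer())
  subs <- data.table::rbindlist(c(list(proto), subs))
  all_ids <- subs$id

  base <- as.POSIXct(sprintf("%d-01-01 00:00:00", config$year), tz = "UTC")
  recs <- list()
  for (ci in seq_len(nrow(cities))) {
    city <- cities[ci]
    city_subs <- subs[home_city == city$id]
    for (coh in seq_len(nrow(cohorts))) {
      members <- city_subs[cohort == coh, id]
      if (!length(members)) next
      for (d in days) {
        set.seed(.block_seed(config$seed, ci, d, coh))
        lam <- daily_intensity(config, city, cohorts[coh], d)
        ev <- sample_calls(lam, length(members))
        if (!nrow(ev)) next
        recs[[length(recs) + 1]] <- data.table::data.table(
          caller_id = members[ev$user],
          callee_id = all_ids[sample.int(length(all_ids), nrow(ev),
                                         replace = TRUE)],
          start = base + round((d - 1) * 86400 + ev$t * 3600),
          duration_s = round(stats::rexp(nrow(ev), 1 / 120)))
      }
    }
  }
  records <- data.table::rbindlist(recs)
  if (!nrow(records))
    records <- data.table::data.table(caller_id = character(),
                                      callee_id = character(),
                                      start = base[0],
                                      duration_s = numeric())
  data.table::setorder(records, start, caller_id)

  truth <- list(
    cities = data.table::data.table(
      id = cities$id,
      injected_phase_min = transit_delay(cities$rel_longitude, 0)),
    cohorts = cohorts[, .(age_lo, age_hi, gender, t_mid_offset_min)],
    seasonal_amplitude = config$seasonal_amplitude)

  out <- list(records = records,
              subscribers = subs[, !"cohort"],
              cities = cities, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(cdr = file.path(dir, "cdr.csv"),
                  subscribers = file.path(dir, "subscribers.csv"),
                  cities = file.path(dir, "cities.csv"),
                  truth_cities = file.path(dir, "truth_cities.csv"),
                  truth_cohorts = file.path(dir, "truth_cohorts.csv"))
    write_cdr(records, paths$cdr)
    data.table::fwrite(out$subscribers, paths$subscribers)
    data.table::fwrite(cities, paths$cities)
    data.table::fwrite(truth$cities, paths$truth_cities)
    data.table::fwrite(truth$cohorts, paths$truth_cohorts)
    out$paths <- paths
  }
  invisible(out)
}

# largest-remainder integer allocation of n into proportions p
.allocate <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
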