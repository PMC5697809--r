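ts <- function(s) as.POSIXct(s, tz = "UTC")

test_that("activity days run from 04:00 to 03:59 of the next calendar day", {
  aug1 <- as.integer(format(as.Date("2007-08-01"), "%j"))
  res <- assign_activity_day(ts(c("2007-08-02 03:30:00",
                                  "2007-08-02 04:00:00",
                                  "2007-08-02 12:15:00")))
  expect_equal(res$day, c(aug1, aug1 + 1, aug1 + 1))
  expect_equal(res$extended_hour, c(27.5, 4.0, 12.25))
  expect_error(assign_activity_day(ts("2007-01-01 02:00:00")), "outside")
  expect_error(assign_activity_day(ts("2006-12-31 12:00:00")), "study year")
})

test_that("extended hours are bijective with the timestamp", {
  set.seed(11)
  t0 <- ts("2007-01-01 04:00:00") + round(runif(200, 0, 363 * 86400))
  res <- assign_activity_day(t0)
  expect_true(all(res$extended_hour >= 4 & res$extended_hour < 28))
  back <- ts("2007-01-01 00:00:00") +
    (res$day - 1) * 86400 + res$extended_hour * 3600
  expect_equal(as.numeric(back), as.numeric(t0), tolerance = 1e-6)
})

test_that("first/last call extraction respects the 11-h windows", {
  calls <- make_calls(
    a = list(day = 1, t = c(7, 9, 19, 26.5)),     # both windows
    b = list(day = 1, t = c(16.5, 16.75)),        # between windows: neither
    c = list(day = 1, t = c(5, 15.99, 17, 27.99)),# window edges inclusive
    d = list(day = 1, t = c(4.5, 16.45))          # 04:30 and 16:27: neither
  )
  fc <- extract_first_calls(calls)
  lc <- extract_last_calls(calls)
  expect_equal(fc[caller_id == "a", time], 7)
  expect_equal(lc[caller_id == "a", time], 26.5)
  expect_false("b" %in% fc$caller_id)
  expect_false("b" %in% lc$caller_id)
  expect_equal(fc[caller_id == "c", time], 5)
  expect_equal(lc[caller_id == "c", time], 27.99)
  expect_false("d" %in% fc$caller_id)
  expect_false("d" %in% lc$caller_id)
  # the two windows cover 22 of the 24 extended hours and are disjoint
  expect_equal((16 - 5) + (28 - 17), 22)
})

test_that("binned distributions normalize and locate mass correctly", {
  d1 <- binned_distribution(23.0, c(17, 28), 5)
  expect_s3_class(d1, "binned_distribution")
  expect_equal(sum(d1$probs), 1)
  expect_equal(d1$probs[d1$centers > 22.99 & d1$centers < 23.09], 1)

  # uniform times at every bin centre -> uniform probabilities
  d2 <- binned_distribution(seq(17 + 1 / 24, 28 - 1 / 24, by = 1 / 12),
                            c(17, 28), 5)
  expect_true(all(abs(d2$probs - 1 / 132) < 1e-12))

  expect_error(binned_distribution(16.9, c(17, 28), 5), "inside the window")
  empty <- binned_distribution(numeric(), c(17, 28), 5)
  expect_equal(empty$n_events, 0)
  expect_true(all(empty$probs == 0))
  expect_error(mean_time(empty), "undefined")
})

test_that("sampled bin probabilities match the generator's intensity", {
  cfg <- generator_config(seed = 5)
  lam <- daily_intensity(cfg, cfg$cities[4], NULL, 10)
  set.seed(99)
  ev <- sample_calls(lam, 3000)
  d <- binned_distribution(ev$t, c(4, 28), 30)
  # expected bin mass from the analytic intensity integral
  expected <- vapply(seq_along(d$probs), function(i) {
    stats::integrate(lam, d$breaks[i], d$breaks[i + 1])$value
  }, numeric(1)) / attr(lam, "integral")
  se <- sqrt(expected * (1 - expected) / d$n_events)
  expect_true(all(abs(d$probs - expected) < 3.5 * se + 1e-9))
})

test_that("mean_time is the probability-weighted bin centre", {
  d <- binned_distribution(rep(23.0 + 1 / 24, 10), c(17, 28), 5)
  expect_equal(mean_time(d), 23.0 + 1 / 24)
  sym <- binned_distribution(c(21.9, 22.1), c(17, 28), 5)
  expect_equal(mean_time(sym), 22.0)
  wt <- binned_distribution(c(20, 24, 24, 24) + 1 / 24, c(17, 27), 120)
  expect_equal(mean_time(wt), 23.0)
})

test_that("shifting a distribution shifts its mean by the same amount", {
  set.seed(3)
  for (i in 1:10) {
    d <- binned_distribution(runif(200, 19, 25), c(17, 28), 5)
    s <- sample(c(-3, -1, 2, 4), 1) * 5
    expect_equal(mean_time(shift_distribution(d, s)),
                 mean_time(d) + s / 60, tolerance = 1e-9)
  }
})

test_that("daily timing series stays inside the window invariants", {
  cfg <- generator_config(seed = 8, users_per_city = 150,
                          cities = default_band_cities()[4])
  ds <- generate_dataset(cfg, days = 1:7)
  ad <- assign_activity_day(ds$records$start)
  calls <- data.table::data.table(caller_id = ds$records$caller_id,
                                  day = ad$day,
                                  extended_hour = ad$extended_hour,
                                  city = "ref")
  sr <- daily_timing_series(calls)
  expect_equal(nrow(sr), 7)
  expect_true(all(sr$t_F >= 5 & sr$t_F < 16))
  expect_true(all(sr$t_L >= 17 & sr$t_L < 28))
  expect_equal(as.character(sr$weekday[1:7]),
               c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"))
})

test_that("pooled all-call distribution is bimodal with an afternoon trough", {
  cfg <- generator_config(seed = 2, users_per_city = 400,
                          cities = default_band_cities()[4])
  ds <- generate_dataset(cfg, days = 8:14)
  ad <- assign_activity_day(ds$records$start)
  d <- binned_distribution(ad$extended_hour, c(4, 28), 30)
  v <- stats::filter(d$probs, rep(1 / 3, 3))  # light smoothing
  v[c(1, length(v))] <- d$probs[c(1, length(v))]
  i <- 2:(length(v) - 1)
  maxima <- d$centers[i[v[i] > v[i - 1] & v[i] > v[i + 1]]]
  expect_gte(sum(maxima > 9 & maxima < 15), 1)   # morning peak
  expect_gte(sum(maxima > 17 & maxima < 23), 1)  # evening peak
  # interior trough between the peaks, in [15, 17) extended hours
  mid <- d$centers > 14 & d$centers < 18
  trough <- d$centers[mid][which.min(d$probs[mid])]
  expect_gte(trough, 15)
  expect_lte(trough, 17)
})
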