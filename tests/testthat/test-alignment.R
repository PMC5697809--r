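mkdist <- function(probs, n = 1000, window = c(17, 28), bin_width = NULL) {
  nb <- length(probs)
  if (is.null(bin_width)) bin_width <- (window[2] - window[1]) * 60 / nb
  wh <- bin_width / 60
  structure(list(window = window, bin_width = bin_width,
                 breaks = window[1] + (0:nb) * wh,
                 centers = window[1] + (seq_len(nb) - 0.5) * wh,
                 probs = probs / sum(probs), n_events = n),
            class = "binned_distribution")
}

test_that("KL divergence matches hand-computed values and is asymmetric", {
  p <- mkdist(c(0.5, 0.5), window = c(17, 27))
  q <- mkdist(c(0.25, 0.75), window = c(17, 27))
  expect_equal(kl_divergence(p, p), 0)
  expect_equal(kl_divergence(p, q), 0.5 * log(2) + 0.5 * log(2 / 3))
  expect_equal(kl_divergence(p, q), 0.14384, tolerance = 1e-4)
  expect_equal(kl_divergence(q, p), 0.25 * log(0.5) + 0.75 * log(1.5))
  expect_equal(kl_divergence(q, p), 0.13081, tolerance = 1e-4)
  bad <- mkdist(c(0.5, 0.5), window = c(5, 16))
  expect_error(kl_divergence(p, bad), "same window")
})

test_that("KL divergence is non-negative and zero only at equality", {
  set.seed(21)
  for (i in 1:50) {
    p <- smooth_distribution(binned_distribution(runif(60, 18, 26),
                                                 c(17, 28), 5))
    q <- smooth_distribution(binned_distribution(runif(60, 18, 26),
                                                 c(17, 28), 5))
    expect_gte(kl_divergence(p, q), 0)
    expect_equal(kl_divergence(p, p), 0)
  }
})

test_that("shift_distribution moves mass and renormalizes at the edge", {
  d <- binned_distribution(23.0 + 1 / 24, c(17, 28), 5)
  expect_equal(shift_distribution(d, 0)$probs, d$probs)
  s <- shift_distribution(d, 15)
  expect_equal(mean_time(s), 23.25 + 1 / 24)
  expect_equal(s$n_events, d$n_events)
  # mass within 10 min of the window end pushed 20 min out: the remainder
  # renormalizes to 1
  e <- binned_distribution(c(27.9, 20.04), c(17, 28), 5)
  shifted <- shift_distribution(e, 20)
  expect_equal(sum(shifted$probs), 1)
  expect_equal(mean_time(shifted), 20 + 20 / 60 + 1 / 24)
  expect_error(shift_distribution(d, 7), "multiple")
})

test_that("best_shift recovers exact and quantized injected delays", {
  set.seed(4)
  times <- rnorm(5000, 22, 1.5)
  times <- times[times >= 17 & times < 27]
  p_ref <- binned_distribution(times, c(17, 28), 5)
  expect_equal(best_shift(p_ref, p_ref)$shift_min, 0)
  # candidate delayed by exactly 15 min
  p_c <- binned_distribution(times + 0.25, c(17, 28), 5)
  expect_equal(best_shift(p_ref, p_c)$shift_min, 15)
  # 31.2-min (unquantized) delay snaps to the nearest 5-min grid point
  p_c2 <- binned_distribution(times + 31.2 / 60, c(17, 28), 5)
  expect_equal(best_shift(p_ref, p_c2)$shift_min, 30)
})

test_that("best_shift is equivariant under extra one-step delays", {
  set.seed(9)
  times <- rnorm(4000, 21.5, 1.2)
  times <- times[times >= 17.5 & times < 26]
  p_ref <- binned_distribution(times, c(17, 28), 5)
  for (k in 0:5) {
    p_c <- binned_distribution(times + k * 5 / 60, c(17, 28), 5)
    expect_equal(best_shift(p_ref, p_c)$shift_min, k * 5)
  }
})

test_that("best_shift and kl_divergence agree with brute-force oracles", {
  set.seed(31)
  for (i in 1:30) {
    p <- binned_distribution(runif(80, 18, 27), c(17, 28), 5)
    q_t <- runif(80, 18, 26.5) + sample(-3:5, 1) * 5 / 60
    q <- binned_distribution(q_t, c(17, 28), 5)
    sp <- smooth_distribution(p)
    sq <- smooth_distribution(q)
    expect_equal(kl_divergence(sp, sq), brute_kl(sp$probs, sq$probs))
    got <- best_shift(p, q)
    want <- brute_best_shift(p, q)
    expect_equal(got$shift_min, want$shift_min)
    expect_equal(got$divergence, want$divergence)
  }
})

test_that("weekly averages use the population standard deviation", {
  res <- data.table::data.table(day = c(1, 8, 15, 22),
                                shift_min = c(15, 15, 15, 15))
  out <- weekly_average_shifts(res)
  expect_equal(out$mean_shift_min, 15)
  expect_equal(out$std_shift_min, 0)
  expect_equal(out$n_days, 4L)
  res2 <- data.table::data.table(day = c(2, 9), shift_min = c(10, 20))
  out2 <- weekly_average_shifts(res2)
  expect_equal(out2$mean_shift_min, 15)
  expect_equal(out2$std_shift_min, 5)  # n-denominator form
  # holiday filtering drops the day before averaging
  out3 <- weekly_average_shifts(res2, holidays = 9)
  expect_equal(out3$n_days, 1L)
  expect_equal(out3$mean_shift_min, 10)
})

test_that("shift grid defaults span -25..+40 min in 14 candidates", {
  g <- shift_grid()
  expect_equal(g$n_max - g$n_min + 1, 14L)
  expect_equal(g$n_min * g$delta, -25)
  expect_equal(g$n_max * g$delta, 40)
  expect_error(shift_grid(2, 8), "n_min")
})

test_that("band alignment recovers injected phases and the null case", {
  cfg <- generator_config(seed = 12, users_per_city = 400,
                          cities = default_band_cities()[c(1, 4)])
  ds <- generate_dataset(cfg, days = 1:21)
  ad <- assign_activity_day(ds$records$start)
  calls <- data.table::data.table(
    caller_id = ds$records$caller_id, day = ad$day,
    extended_hour = ad$extended_hour,
    city = ds$subscribers$home_city[match(ds$records$caller_id,
                                          ds$subscribers$id)])
  rep <- band_alignment_report(calls, ds$cities, "ref")
  expect_true(all(rep[city == "ref", mean_shift_min] == 0))
  expect_equal(unique(rep[city == "west1", expected_transit_delay_min]),
               31.2)
  m <- rep[city == "west1", mean(mean_shift_min), by = which]$V1
  expect_true(all(abs(m - 31.2) <= 7.5))

  # phase injection off (single-city band vs itself shifted by nothing):
  # all shifts collapse to zero within one grid step
  cfg0 <- generator_config(seed = 12, users_per_city = 400,
                           cities = {
                             cc <- default_band_cities()[c(1, 4)]
                             cc$rel_longitude <- 0
                             cc$center_lon <- c(-7.8, 0)
                             cc
                           })
  ds0 <- generate_dataset(cfg0, days = 1:21)
  ad0 <- assign_activity_day(ds0$records$start)
  calls0 <- data.table::data.table(
    caller_id = ds0$records$caller_id, day = ad0$day,
    extended_hour = ad0$extended_hour,
    city = ds0$subscribers$home_city[match(ds0$records$caller_id,
                                           ds0$subscribers$id)])
  rep0 <- band_alignment_report(calls0, ds0$cities, "ref")
  null_means <- rep0[, .(m = mean(mean_shift_min)), by = .(city, which)]$m
  expect_true(all(abs(null_means) <= 5))
})
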