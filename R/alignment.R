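#' Discrete shift grid for distribution alignment
#'
#' Candidate time shifts `n * delta` minutes, `n_min <= n <= n_max`. The
#' defaults (-5..8 steps of 5 min, 14 candidates, -25 to +40 min) cover
#' the sun-transit delays arising within a ~11-degree-wide longitudinal
#' band.
#'
#' @param n_min,n_max Integer step range, `n_min <= 0 <= n_max`.
#' @param delta Step size in minutes.
#' @return A list of class `shift_grid`.
#' @export
shift_grid <- function(n_min = -5L, n_max = 8L, delta = 5) {
  stopifnot(n_min <= 0, n_max >= 0, delta > 0)
  structure(list(n_min = as.integer(n_min), n_max = as.integer(n_max),
                 delta = delta),
            class = "shift_grid")
}

.check_same_binning <- function(p, q) {
  stopifnot(inherits(p, "binned_distribution"),
            inherits(q, "binned_distribution"))
  if (!isTRUE(all.equal(p$window, q$window)) || p$bin_width != q$bin_width)
    stop("distributions must share the same window and bin width")
}

#' Kullback-Leibler divergence between binned distributions
#'
#' `D_KL(P, Q) = sum_i P_i log(P_i / Q_i)` in nats, over a common binning.
#' Terms with `P_i = 0` contribute zero; a bin with `P_i > 0` but
#' `Q_i = 0` makes the divergence infinite, so distributions estimated
#' from counts should be smoothed first (see [smooth_distribution()], as
#' [best_shift()] does internally).
#'
#' @param p,q [binned_distribution()] objects with identical binning, or
#'   bare probability vectors of equal length.
#' @return Non-negative divergence in nats; 0 iff `p == q`.
#' @export
kl_divergence <- function(p, q) {
  if (inherits(p, "binned_distribution")) {
    .check_same_binning(p, q)
    p <- p$probs; q <- q$probs
  }
  if (length(p) != length(q))
    stop("probability vectors must have equal length")
  i <- p > 0
  if (any(q[i] == 0)) return(Inf)
  sum(p[i] * log(p[i] / q[i]))
}

#' Additive smoothing of a binned distribution
#'
#' Adds a pseudocount `alpha` to every bin count and renormalizes, making
#' all probabilities strictly positive so KL divergences stay finite.
#' Applied identically to both distributions before divergence evaluation.
#'
#' @param dist A [binned_distribution()] with `n_events > 0`.
#' @param alpha Pseudocount per bin (default 0.5).
#' @return A smoothed `binned_distribution`.
#' @export
smooth_distribution <- function(dist, alpha = 0.5) {
  stopifnot(inherits(dist, "binned_distribution"), dist$n_events > 0)
  counts <- dist$probs * dist$n_events + alpha
  dist$probs <- counts / sum(counts)
  dist
}

#' Shift a binned distribution in time
#'
#' Moves all probability mass `shift` minutes later (a positive shift
#' delays the distribution; negative advances it). The shift must be a
#' whole number of bins. Mass pushed beyond the window is dropped and the
#' remainder renormalized -- the windows are wide (11 h) relative to the
#' grid's <= 40-min shifts, so the dropped mass is negligible in practice.
#' `n_events` is preserved.
#'
#' @param dist A [binned_distribution()].
#' @param shift Minutes, an integer multiple of `dist$bin_width`.
#' @return A shifted `binned_distribution`.
#' @export
shift_distribution <- function(dist, shift) {
  stopifnot(inherits(dist, "binned_distribution"))
  k <- shift / dist$bin_width
  if (abs(k - round(k)) > 1e-9)
    stop("shift must be an integer multiple of the bin width")
  k <- round(k)
  nb <- length(dist$probs)
  new <- numeric(nb)
  if (k >= 0) {
    if (k < nb) new[(1 + k):nb] <- dist$probs[1:(nb - k)]
  } else {
    if (-k < nb) new[1:(nb + k)] <- dist$probs[(1 - k):nb]
  }
  s <- sum(new)
  if (s > 0) new <- new / s
  dist$probs <- new
  dist
}

#' Best time shift between a reference and a candidate distribution
#'
#' Evaluates, for every grid step `n`, the divergence
#' `D_KL(P_ref, P_c(t + n*delta))` -- i.e. the candidate advanced by
#' `n*delta` minutes -- and returns the minimizing shift. A positive best
#' shift means the candidate city's activity lags the reference by that
#' many minutes (as for cities further west). Ties are broken toward the
#' smallest `|n|`, then toward negative `n`.
#'
#' @param p_ref,p_c Reference and candidate [binned_distribution()]s,
#'   identical binning, both non-empty.
#' @param grid A [shift_grid()]; `delta` must be a multiple of the bin
#'   width.
#' @param alpha Smoothing pseudocount passed to [smooth_distribution()].
#' @return A list `shift_min` (best `n*delta`, minutes), `n`,
#'   `divergence` (at the best shift), `divergences` (full grid, named by
#'   `n`).
#' @export
best_shift <- function(p_ref, p_c, grid = shift_grid(), alpha = 0.5) {
  .check_same_binning(p_ref, p_c)
  if (p_ref$n_events == 0 || p_c$n_events == 0)
    stop("cannot align an empty distribution")
  ref <- smooth_distribution(p_ref, alpha)
  ns <- grid$n_min:grid$n_max
  div <- vapply(ns, function(n) {
    cand <- smooth_distribution(shift_distribution(p_c, -n * grid$delta),
                                alpha)
    kl_divergence(ref, cand)
  }, numeric(1))
  # ties: smallest |n| first, then negative n
  ord <- order(div, abs(ns), ns)
  best <- ord[1]
  list(shift_min = ns[best] * grid$delta, n = ns[best],
       divergence = div[best],
       divergences = stats::setNames(div, ns))
}

#' Weekday-wise average of daily best shifts
#'
#' Averages daily alignment shifts separately per day of the week (calling
#' timings differ systematically across weekdays). The spread is the
#' population standard deviation.
#'
#' @param results Data.frame with columns `day` and `shift_min` (and
#'   optionally grouping columns `city`, `which`, preserved).
#' @param year Study year, for weekday labels.
#' @param holidays Optional integer vector of day indices to drop first.
#' @return A `data.table` with `weekday`, `mean_shift_min`,
#'   `std_shift_min`, `n_days` per group.
#' @export
weekly_average_shifts <- function(results, year = 2007,
                                  holidays = integer()) {
  res <- data.table::as.data.table(results)
  res <- res[!day %in% holidays]
  res[, weekday := day_of_week(day, year)]
  by_cols <- intersect(c("city", "which", "weekday"), names(res))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- res[, .(mean_shift_min = mean(shift_min),
                 std_shift_min = pop_sd(shift_min),
                 n_days = .N), by = by_cols]
  data.table::setorderv(out, by_cols)
  out[]
}

#' Band-wide alignment report
#'
#' For every city in a latitudinal band, aligns its daily first-call and
#' last-call distributions against the band's reference city by KL-shift
#' minimization, averages per weekday, and juxtaposes the expected
#' sun-transit delay implied by the city's relative longitude.
#'
#' @param calls Data.frame `city, caller_id, day, extended_hour` covering
#'   the band's cities.
#' @param cities City registry rows (needs `id`, `rel_longitude`).
#' @param reference_id Id of the band's reference city.
#' @param grid A [shift_grid()].
#' @param bin_width Histogram bin width in minutes.
#' @param year Study year.
#' @param holidays Day indices excluded from the weekday averages.
#' @param alpha Smoothing pseudocount.
#' @return A `data.table` `city, weekday, which, mean_shift_min,
#'   std_shift_min, n_days, expected_transit_delay_min` with
#'   `which` in {"first", "last"}.
#' @export
band_alignment_report <- function(calls, cities, reference_id,
                                  grid = shift_grid(), bin_width = 5,
                                  year = 2007, holidays = integer(),
                                  alpha = 0.5) {
  cities <- data.table::as.data.table(cities)
  if (!reference_id %in% cities$id)
    stop("reference city '", reference_id, "' not in the city table")
  ref_lon <- cities[id == reference_id, rel_longitude]
  sets <- list(first = list(fun = extract_first_calls,
                            window = .MORNING_WINDOW),
               last = list(fun = extract_last_calls,
                           window = .NIGHT_WINDOW))
  daily <- list()
  for (w in names(sets)) {
    ev <- sets[[w]]$fun(calls)
    win <- sets[[w]]$window
    dists <- ev[, .(dist = list(binned_distribution(time, win, bin_width))),
                by = .(city, day)]
    refs <- dists[city == reference_id, .(day, ref_dist = dist)]
    cand <- merge(dists[city != reference_id], refs, by = "day")
    if (nrow(cand)) {
      sm <- vapply(seq_len(nrow(cand)), function(i) {
        p_ref <- cand$ref_dist[[i]]; p_c <- cand$dist[[i]]
        if (p_ref$n_events == 0 || p_c$n_events == 0) return(NA_real_)
        best_shift(p_ref, p_c, grid, alpha)$shift_min
      }, numeric(1))
      shifts <- data.table::data.table(city = cand$city, day = cand$day,
                                       shift_min = sm, which = w)
      daily[[w]] <- shifts[!is.na(shift_min)]
    }
  }
  daily <- data.table::rbindlist(daily)
  # the reference vs itself: zero by construction, included for completeness
  ref_rows <- data.table::CJ(city = reference_id,
                             day = sort(unique(calls$day)),
                             which = names(sets))
  ref_rows[, shift_min := 0]
  daily <- rbind(daily, ref_rows, use.names = TRUE)
  out <- weekly_average_shifts(daily, year = year, holidays = holidays)
  out[, expected_transit_delay_min :=
        transit_delay(cities[match(out$city, id), rel_longitude], ref_lon)]
  data.table::setorder(out, which, city, weekday)
  out[]
}
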