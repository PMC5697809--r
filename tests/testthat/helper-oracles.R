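# Independent reference implementations used as oracles. These are kept
# deliberately naive (plain loops, different formulas) so they share no
# code path with the package.

# spherical law of cosines distance, R = 6371 km
slc_distance_km <- function(a, b) {
  to_rad <- pi / 180
  la1 <- a[1] * to_rad; lo1 <- a[2] * to_rad
  la2 <- b[1] * to_rad; lo2 <- b[2] * to_rad
  ang <- sin(la1) * sin(la2) + cos(la1) * cos(la2) * cos(lo2 - lo1)
  6371 * acos(pmin(1, pmax(-1, ang)))
}

# KL divergence by an explicit loop
brute_kl <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) s <- s + p[i] * log(p[i] / q[i])
  }
  s
}

# naive best-shift search: smooth, shift by copying bins one by one,
# renormalize, accumulate the KL sum, track the minimum with the
# smallest-|n|-then-negative tie rule
brute_best_shift <- function(p_ref, p_c, n_min = -5, n_max = 8, delta = 5,
                             alpha = 0.5) {
  smooth <- function(probs, n_events) {
    counts <- probs * n_events + alpha
    counts / sum(counts)
  }
  nb <- length(p_ref$probs)
  ref <- smooth(p_ref$probs, p_ref$n_events)
  best_n <- NA
  best_d <- Inf
  for (n in n_min:n_max) {
    k <- -n * delta / p_c$bin_width  # advance candidate by n*delta
    shifted <- rep(0, nb)
    for (i in seq_len(nb)) {
      j <- i + k
      if (j >= 1 && j <= nb) shifted[j] <- p_c$probs[i]
    }
    if (sum(shifted) > 0) shifted <- shifted / sum(shifted)
    cand <- smooth(shifted, p_c$n_events)
    d <- brute_kl(ref, cand)
    better <- d < best_d ||
      (d == best_d && (abs(n) < abs(best_n) ||
                         (abs(n) == abs(best_n) && n < best_n)))
    if (better) {
      best_d <- d
      best_n <- n
    }
  }
  list(shift_min = best_n * delta, divergence = best_d)
}

# NOAA solar-position spreadsheet formulas (Meeus-based Julian-century
# polynomials) -- algorithmically unrelated to the package's Spencer
# Fourier series. Year 2007; returns declination (deg) and equation of
# time (min) at local mean noon.
noaa_solar <- function(d) {
  jd <- 2454101.5 + (d - 1) + 0.5
  t <- (jd - 2451545) / 36525
  rad <- pi / 180
  gml <- (280.46646 + t * (36000.76983 + 0.0003032 * t)) %% 360
  gma <- 357.52911 + t * (35999.05029 - 0.0001537 * t)
  ecc <- 0.016708634 - t * (0.000042037 + 0.0000001267 * t)
  ctr <- sin(gma * rad) * (1.914602 - t * (0.004817 + 0.000014 * t)) +
    sin(2 * gma * rad) * (0.019993 - 0.000101 * t) +
    sin(3 * gma * rad) * 0.000289
  stl <- gml + ctr
  omega <- 125.04 - 1934.136 * t
  sal <- stl - 0.00569 - 0.00478 * sin(omega * rad)
  moe <- 23 + (26 + (21.448 - t * (46.815 + t * (0.00059 - t * 0.001813))) /
                 60) / 60
  oc <- moe + 0.00256 * cos(omega * rad)
  decl <- asin(sin(oc * rad) * sin(sal * rad)) / rad
  y <- tan(oc / 2 * rad)^2
  eot <- 4 / rad * (y * sin(2 * gml * rad) - 2 * ecc * sin(gma * rad) +
                      4 * ecc * y * sin(gma * rad) * cos(2 * gml * rad) -
                      0.5 * y^2 * sin(4 * gml * rad) -
                      1.25 * ecc^2 * sin(2 * gma * rad))
  list(declination = decl, eot = eot)
}

# rise/set/transit clock hours from the NOAA quantities (standard time,
# meridian-relative longitude, no DST)
noaa_rise_set <- function(lat, d) {
  o <- noaa_solar(d)
  rad <- pi / 180
  cosH <- (cos(90.833 * rad) - sin(lat * rad) * sin(o$declination * rad)) /
    (cos(lat * rad) * cos(o$declination * rad))
  H <- acos(cosH) / rad
  transit <- 12 - o$eot / 60
  list(sunrise = transit - H / 15, transit = transit,
       sunset = transit + H / 15)
}

# small in-memory call table builder: times are extended hours
make_calls <- function(..., city = NULL) {
  users <- list(...)
  dt <- data.table::rbindlist(lapply(names(users), function(u) {
    data.table::data.table(caller_id = u, day = users[[u]]$day,
                           extended_hour = users[[u]]$t)
  }))
  if (!is.null(city)) dt[, city := city]
  dt
}
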