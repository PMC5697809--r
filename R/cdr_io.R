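#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km (via
#' \pkg{geosphere}). Inputs are `(lat, lon)` pairs in degrees, the order
#' used throughout this package.
#'
#' @param a,b Numeric `c(lat, lon)` vectors, or two-column matrices of
#'   `(lat, lon)` rows (recycled against each other row-wise).
#' @return Non-negative distance(s) in km; symmetric in its arguments.
#' @export
haversine_km <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  .check_coords(a); .check_coords(b)
  # geosphere expects (lon, lat)
  geosphere::distHaversine(a[, 2:1, drop = FALSE], b[, 2:1, drop = FALSE],
                           r = 6371000) / 1000
}

.check_coords <- function(m) {
  if (ncol(m) != 2 || anyNA(m))
    stop("coordinates must be complete (lat, lon) pairs")
  if (any(abs(m[, 1]) > 90) || any(abs(m[, 2]) > 180))
    stop("latitude must lie in [-90, 90] and longitude in [-180, 180]")
  invisible(m)
}

#' Does a subscriber reside in a city?
#'
#' A subscriber counts as living in a city when all three hold, each with a
#' strict inequality:
#' \enumerate{
#'   \item most-accessed cell tower (MAC-tower) to city centre < 15 km,
#'   \item postal-code centroid to city centre < 15 km,
#'   \item MAC-tower to postal centroid < 30 km.
#' }
#'
#' @param tower,postal,center `(lat, lon)` pairs (or matrices) for the
#'   MAC-tower, the postal centroid and the city centre.
#' @param max_tower_km,max_postal_km,max_pair_km Distance thresholds;
#'   defaults 15, 15 and 30 km.
#' @return Logical vector; `NA` where any coordinate is missing.
#' @export
resides_in_city <- function(tower, postal, center,
                            max_tower_km = 15, max_postal_km = 15,
                            max_pair_km = 30) {
  tower <- rbind(tower); postal <- rbind(postal); center <- rbind(center)
  n <- max(nrow(tower), nrow(postal), nrow(center))
  idx <- function(m) m[rep_len(seq_len(nrow(m)), n), , drop = FALSE]
  tower <- idx(tower); postal <- idx(postal); center <- idx(center)
  ok <- stats::complete.cases(tower) & stats::complete.cases(postal) &
    stats::complete.cases(center)
  res <- rep(NA, n)
  if (any(ok)) {
    res[ok] <- haversine_km(tower[ok, , drop = FALSE], center[ok, , drop = FALSE]) < max_tower_km &
      haversine_km(postal[ok, , drop = FALSE], center[ok, , drop = FALSE]) < max_postal_km &
      haversine_km(tower[ok, , drop = FALSE], postal[ok, , drop = FALSE]) < max_pair_km
  }
  res
}

#' CDR file schema
#'
#' Column names and timestamp format of a call-detail-record CSV; CDR
#' exports differ between providers, so the mapping is configurable.
#'
#' @param caller_id,callee_id,start,duration Column names in the file.
#' @param timestamp_format `strptime()` format of the `start` column;
#'   timestamps are provider-local civil clock time and are kept as such
#'   (stored with tz "UTC" purely as a fixed-offset container).
#' @return A list of class `cdr_schema`.
#' @export
cdr_schema <- function(caller_id = "caller_id", callee_id = "callee_id",
                       start = "start", duration = "duration_s",
                       timestamp_format = "%Y-%m-%d %H:%M:%S") {
  structure(list(caller_id = caller_id, callee_id = callee_id,
                 start = start, duration = duration,
                 timestamp_format = timestamp_format),
            class = "cdr_schema")
}

#' Read call detail records
#'
#' Reads a CSV of outgoing-call events. Rows whose timestamp does not parse
#' or whose duration is negative/missing are dropped and counted; row order
#' is preserved.
#'
#' @param path CSV file with a header row.
#' @param schema A [cdr_schema()].
#' @return A `data.table` with columns `caller_id`, `callee_id`, `start`
#'   (POSIXct, civil clock time), `duration_s`; the number of dropped rows
#'   is in `attr(, "n_skipped")`.
#' @export
read_cdr <- function(path, schema = cdr_schema()) {
  dt <- data.table::fread(path, colClasses = list(
    character = c(schema$caller_id, schema$callee_id)))
  for (col in c(schema$caller_id, schema$callee_id, schema$start,
                schema$duration)) {
    if (!col %in% names(dt))
      stop(sprintf("CDR file %s is missing mandatory column '%s'", path, col))
  }
  out <- data.table::data.table(
    caller_id = as.character(dt[[schema$caller_id]]),
    callee_id = as.character(dt[[schema$callee_id]]),
    start = as.POSIXct(as.character(dt[[schema$start]]),
                       format = schema$timestamp_format, tz = "UTC"),
    duration_s = as.numeric(dt[[schema$duration]]))
  bad <- is.na(out$start) | is.na(out$duration_s) | out$duration_s < 0
  res <- out[!bad]
  data.table::setattr(res, "n_skipped", sum(bad))
  res[]
}

#' Write call detail records
#'
#' Inverse of [read_cdr()]: `read_cdr(write_cdr(x, f))` round-trips a valid
#' record stream.
#'
#' @param records A data.frame as returned by [read_cdr()].
#' @param path Output CSV path.
#' @param schema A [cdr_schema()].
#' @return `path`, invisibly.
#' @export
write_cdr <- function(records, path, schema = cdr_schema()) {
  out <- data.table::data.table(
    caller_id = records$caller_id, callee_id = records$callee_id,
    start = format(records$start, schema$timestamp_format, tz = "UTC"),
    duration_s = records$duration_s)
  data.table::setnames(out, c(schema$caller_id, schema$callee_id,
                              schema$start, schema$duration))
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read the subscriber demographics table
#'
#' Expected columns: `id, age, gender, postal_lat, postal_lon, tower_lat,
#' tower_lon, home_city`.
#'
#' @param path CSV path.
#' @return A `data.table`, `gender` normalized to
#'   {"female", "male", "unknown"}.
#' @export
read_subscribers <- function(path) {
  dt <- data.table::fread(path, colClasses = list(
    character = c("id", "home_city")))
  need <- c("id", "age", "gender", "postal_lat", "postal_lon",
            "tower_lat", "tower_lon", "home_city")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("subscribers file is missing column(s): ", paste(miss, collapse = ", "))
  dt[, gender := ifelse(gender %in% c("female", "male"), gender, "unknown")]
  dt[]
}

#' Read the city registry
#'
#' Expected columns: `id, band_latitude, band_halfwidth, rel_longitude,
#' population, center_lat, center_lon`. Latitudes are band centres and
#' longitudes are relative to an undisclosed in-band reference point, the
#' usual masking convention for NDA-protected CDR geographies.
#'
#' @param path CSV path.
#' @return A `data.table`.
#' @export
read_cities <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = "id"))
  need <- c("id", "band_latitude", "band_halfwidth", "rel_longitude",
            "population", "center_lat", "center_lon")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("cities file is missing column(s): ", paste(miss, collapse = ", "))
  if (any(dt$band_halfwidth <= 0) || any(dt$population <= 0))
    stop("band_halfwidth and population must be positive")
  dt[]
}

#' Assign subscribers to study cities
#'
#' Keeps cities above a population threshold and assigns each subscriber to
#' its declared home city only if the three-distance residence rule
#' ([resides_in_city()]) holds. Subscribers failing any rule (or with
#' missing coordinates) stay in the table with `city = NA` and a reason.
#'
#' @param subscribers Table from [read_subscribers()].
#' @param cities Table from [read_cities()].
#' @param min_population Strict lower population bound for a city to enter
#'   the study (default 100,000).
#' @return A `data.table` `id, city, reason` where `reason` is `"ok"`,
#'   `"city_too_small"`, `"missing_coordinates"`, `"fails_residence_rule"`
#'   or `"unknown_city"`.
#' @export
filter_study_population <- function(subscribers, cities,
                                    min_population = 1e5) {
  subscribers <- data.table::as.data.table(subscribers)
  cities <- data.table::as.data.table(cities)
  keep <- cities[population > min_population]
  res <- data.table::data.table(id = subscribers$id,
                                city = NA_character_,
                                reason = "unknown_city")
  m <- match(subscribers$home_city, cities$id)
  known <- !is.na(m)
  small <- known & !(subscribers$home_city %in% keep$id)
  res[small, reason := "city_too_small"]
  cand <- known & !small
  if (any(cand)) {
    ok <- resides_in_city(
      tower = cbind(subscribers$tower_lat, subscribers$tower_lon)[cand, , drop = FALSE],
      postal = cbind(subscribers$postal_lat, subscribers$postal_lon)[cand, , drop = FALSE],
      center = cbind(cities$center_lat, cities$center_lon)[m[cand], , drop = FALSE])
    res[which(cand)[is.na(ok)], reason := "missing_coordinates"]
    res[which(cand)[!is.na(ok) & !ok], reason := "fails_residence_rule"]
    pass <- which(cand)[!is.na(ok) & ok]
    res[pass, `:=`(city = subscribers$home_city[pass], reason = "ok")]
  }
  res[]
}
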