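#' Pipeline configuration
#'
#' Reads (or builds from a list) the configuration driving the pipeline
#' commands. All settings have defaults; a minimal config only names an
#' output directory. See the package vignette for the full layout; the
#' main sections are `paths` (out_dir, cdr, subscribers, cities,
#' holidays), `activity` (bin_width), `alignment` (n_min, n_max, delta,
#' alpha), `clock` ([clock_rules()] fields), `band` (reference_city,
#' latitude), `generate` (users_per_city, day ranges) and `cohorts`
#' (min_users, age range).
#'
#' @param x Path to a YAML file, or a named list.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(x = list()) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("config file not found: ", x)
    cfg <- yaml::read_yaml(x)
    cfg$config_md5 <- unname(tools::md5sum(x))
  } else cfg <- x
  defaults <- list(
    seed = 1L, year = 2007,
    paths = list(out_dir = "urbanrhythm_out"),
    activity = list(bin_width = 5),
    alignment = list(n_min = -5, n_max = 8, delta = 5, alpha = 0.5),
    clock = list(base_utc_offset = 1, dst_start_day = 84,
                 dst_end_day = 301, dst_offset = 1),
    band = list(reference_city = "ref", latitude = 42),
    generate = list(users_per_city = 400, day_first = 1, day_last = 56),
    cohorts = list(min_users = 50, age_min = 18, age_max = 80,
                   age_step = 10, pool_mon_thu = FALSE),
    holidays = integer())
  cfg <- utils::modifyList(defaults, cfg)
  dd <- file.path(cfg$paths$out_dir, "data")
  for (f in c("cdr", "subscribers", "cities")) {
    if (is.null(cfg$paths[[f]]))
      cfg$paths[[f]] <- file.path(dd, paste0(f, ".csv"))
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

.cfg_rules <- function(cfg) do.call(clock_rules, cfg$clock)
.cfg_grid <- function(cfg)
  shift_grid(cfg$alignment$n_min, cfg$alignment$n_max, cfg$alignment$delta)

.log_msg <- function(...) message("[urbanrhythm] ", ...)

.write_output <- function(dt, cfg, name, command) {
  dir.create(cfg$paths$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(cfg$paths$out_dir, paste0(name, ".csv"))
  data.table::fwrite(dt, path)
  manifest <- list(command = command, output = basename(path),
                   rows = nrow(dt), seed = cfg$seed,
                   config_md5 = cfg$config_md5,
                   package_version =
                     as.character(utils::packageVersion("urbanrhythm")))
  jsonlite::write_json(manifest,
                       file.path(cfg$paths$out_dir,
                                 paste0(name, ".manifest.json")),
                       auto_unbox = TRUE, null = "null")
  .log_msg(command, ": wrote ", nrow(dt), " rows to ", path)
  invisible(path)
}

.require_upstream <- function(path, producer) {
  if (!file.exists(path))
    stop("missing input ", path, "; run cmd_", producer, "() first",
         call. = FALSE)
  path
}

.load_study_calls <- function(cfg) {
  recs <- read_cdr(.require_upstream(cfg$paths$cdr, "generate"))
  subs <- read_subscribers(.require_upstream(cfg$paths$subscribers,
                                             "generate"))
  cities <- read_cities(.require_upstream(cfg$paths$cities, "generate"))
  assign <- filter_study_population(subs, cities)
  ad <- assign_activity_day(recs$start, cfg$year)
  calls <- data.table::data.table(
    caller_id = recs$caller_id, day = ad$day,
    extended_hour = ad$extended_hour,
    city = assign$city[match(recs$caller_id, assign$id)])
  list(calls = calls[!is.na(city)], subscribers = subs, cities = cities)
}

#' Pipeline commands
#'
#' Each command reads its inputs, runs one stage of the analysis and
#' writes CSV outputs plus a JSON manifest into `paths$out_dir`. Outputs
#' are deterministic for a fixed seed. `cmd_generate` writes the synthetic
#' dataset; `cmd_distributions` the per-city daily timing series and
#' pooled activity distributions; `cmd_align` the band alignment report;
#' `cmd_solar` the ephemeris and the timing-versus-solar-cue comparison;
#' `cmd_cohorts` the cohort metrics table.
#'
#' @param cfg A [pipeline_config()] (or something coercible by it).
#' @return The path(s) of the written artifacts, invisibly.
#' @export
cmd_generate <- function(cfg) {
  cfg <- pipeline_config(cfg)
  gen <- generator_config(seed = cfg$seed, year = cfg$year,
                          users_per_city = cfg$generate$users_per_city,
                          rules = .cfg_rules(cfg))
  dd <- dirname(cfg$paths$cdr)
  res <- generate_dataset(gen, days = cfg$generate$day_first:
                            cfg$generate$day_last, dir = dd)
  .log_msg("generate: ", nrow(res$records), " call records for ",
           nrow(res$subscribers), " subscribers in ", dd)
  invisible(res$paths)
}

#' @rdname cmd_generate
#' @export
cmd_distributions <- function(cfg) {
  cfg <- pipeline_config(cfg)
  st <- .load_study_calls(cfg)
  timing <- daily_timing_series(st$calls, cfg$year)
  p1 <- .write_output(timing, cfg, "timing", "distributions")
  bw <- cfg$activity$bin_width
  dists <- data.table::rbindlist(lapply(
    split(st$calls, by = "city"), function(cc) {
      fc <- extract_first_calls(cc)
      lc <- extract_last_calls(cc)
      mk <- function(times, win, lab) {
        bd <- binned_distribution(times, win, bw)
        data.table::data.table(city = cc$city[1], which = lab,
                               bin_start_hour = bd$breaks[-length(bd$breaks)],
                               prob = bd$probs)
      }
      rbind(mk(cc$extended_hour, c(4, 28), "all"),
            mk(fc$time, .MORNING_WINDOW, "first"),
            mk(lc$time, .NIGHT_WINDOW, "last"))
    }))
  p2 <- .write_output(dists, cfg, "distributions", "distributions")
  invisible(c(p1, p2))
}

#' @rdname cmd_generate
#' @export
cmd_align <- function(cfg) {
  cfg <- pipeline_config(cfg)
  st <- .load_study_calls(cfg)
  rep <- band_alignment_report(st$calls, st$cities,
                               cfg$band$reference_city,
                               grid = .cfg_grid(cfg),
                               bin_width = cfg$activity$bin_width,
                               year = cfg$year,
                               holidays = unlist(cfg$holidays),
                               alpha = cfg$alignment$alpha)
  invisible(.write_output(rep, cfg, "alignment", "align"))
}

#' @rdname cmd_generate
#' @export
cmd_solar <- function(cfg) {
  cfg <- pipeline_config(cfg)
  rules <- .cfg_rules(cfg)
  cities <- read_cities(.require_upstream(cfg$paths$cities, "generate"))
  timing_path <- file.path(cfg$paths$out_dir, "timing.csv")
  timing <- data.table::fread(.require_upstream(timing_path,
                                                "distributions"),
                              colClasses = list(character = "city"))
  collapsed <- collapse_band(timing, cities, cfg$band$reference_city)
  collapsed <- filter_holidays(collapsed, unlist(cfg$holidays))
  band <- band_average(collapsed)
  ref_lon <- cities[id == cfg$band$reference_city, rel_longitude]
  cmp <- solar_comparison_report(band, cfg$band$latitude, ref_lon, rules)
  p1 <- .write_output(cmp, cfg, "solar_comparison", "solar")
  eph <- solar_ephemeris(cfg$band$latitude, ref_lon, rules = rules)
  p2 <- .write_output(eph, cfg, "ephemeris", "solar")
  invisible(c(p1, p2))
}

#' @rdname cmd_generate
#' @export
cmd_cohorts <- function(cfg) {
  cfg <- pipeline_config(cfg)
  st <- .load_study_calls(cfg)
  cm <- cohort_metrics(st$calls, st$subscribers,
                       age_breaks = seq(cfg$cohorts$age_min,
                                        cfg$cohorts$age_max,
                                        by = cfg$cohorts$age_step),
                       min_users = cfg$cohorts$min_users,
                       pool_mon_thu = isTRUE(cfg$cohorts$pool_mon_thu),
                       year = cfg$year)
  invisible(.write_output(cm, cfg, "cohorts", "cohorts"))
}

#' Run the full pipeline
#'
#' [cmd_generate()] through [cmd_cohorts()] in dependency order.
#'
#' @inheritParams cmd_generate
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(cfg) {
  cfg <- pipeline_config(cfg)
  cmd_generate(cfg)
  cmd_distributions(cfg)
  cmd_align(cfg)
  cmd_solar(cfg)
  cmd_cohorts(cfg)
  invisible(cfg$paths$out_dir)
}
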