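#' Load and validate a trial configuration from YAML
#'
#' Reads a YAML trial description, rejects unknown keys, validates every
#' field through the component constructors and normalizes units: durations
#' and intervals may be written as bare numbers (minutes) or as strings with
#' a unit, e.g. `"30 s"`, `"15 min"`, `"1 h"`.
#'
#' @param path YAML file path.
#' @return a [trial_config()].
#' @examples
#' cfg <- load_config(system.file("extdata", "propofol_reference.yaml",
#'                                package = "isctsim"))
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  check_keys(raw, c("population", "cohort", "tci", "sensor", "actuator",
                    "arms", "output_grid"), "top level")

  p <- raw$population
  check_keys(p, c("means", "omegas", "prop", "add"), "population")
  check_keys(p$means, .pk_param_names, "population$means", require_all = TRUE)
  pop <- population_model(do.call(pk_params, p$means),
                          omegas = unlist(p$omegas),
                          prop = p$prop %||% 0, add = p$add %||% 0)

  co <- raw$cohort
  check_keys(co, c("size", "seed", "demographics"), "cohort")
  demo <- co$demographics %||% list()
  check_keys(demo, c("age", "weight", "height", "sex"), "cohort$demographics")
  demographics <- list(age = demo$age %||% NA, weight_kg = demo$weight %||% NA,
                       height_cm = demo$height %||% NA, sex = demo$sex %||% NA)

  tc <- raw$tci
  check_keys(tc, c("mode", "target", "control_interval", "duration", "max_rate"),
             "tci")
  tci <- tci_config(mode = tc$mode %||% "effect_site", target = tc$target,
                    control_interval = parse_time(tc$control_interval %||% (1 / 6),
                                                  "tci$control_interval"),
                    duration = parse_time(tc$duration, "tci$duration"),
                    max_rate = tc$max_rate)

  se <- raw$sensor %||% list()
  check_keys(se, c("period", "delay", "start", "failure_probability",
                   "failure_mode", "failure_magnitude"), "sensor")
  period_min <- parse_time(se$period %||% "30 s", "sensor$period")
  sched <- measurement_schedule(
    period_s = period_min * 60,
    delay_s = parse_time(se$delay %||% "15 s", "sensor$delay") * 60,
    start_s = parse_time(se$start %||% period_min, "sensor$start") * 60)
  fail <- failure_model(se$failure_probability %||% 0,
                        mode = se$failure_mode %||% "spike",
                        magnitude = se$failure_magnitude %||% 5)

  ac <- raw$actuator
  check_keys(ac, c("max_rate", "min_rate_step", "syringe_volume",
                   "low_reservoir_fraction"), "actuator")
  act <- actuator_config(max_rate = ac$max_rate,
                         min_rate_step = ac$min_rate_step %||% 0,
                         syringe_volume = ac$syringe_volume %||% Inf,
                         low_reservoir_fraction = ac$low_reservoir_fraction %||% 0.1)

  trial_config(population = pop, n = co$size, seed = co$seed, tci = tci,
               sensor = sched, failure = fail, actuator = act,
               arms = unlist(raw$arms) %||% c("open_loop", "closed_loop"),
               demographics = demographics,
               out_dt = parse_time(raw$output_grid %||% 0.1, "output_grid"))
}

check_keys <- function(x, allowed, where, require_all = FALSE) {
  if (is.null(x)) {
    if (require_all) stop("config: missing section '", where, "'", call. = FALSE)
    return(invisible())
  }
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop("config: unknown key(s) in ", where, ": ",
         paste(extra, collapse = ", "), call. = FALSE)
  if (require_all && length(miss <- setdiff(allowed, names(x))))
    stop("config: missing key(s) in ", where, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible()
}

# "30 s" / "0.5 min" / "1 h" / bare number (minutes) -> minutes
parse_time <- function(x, what) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.character(x) && length(x) == 1L) {
    m <- regmatches(x, regexec("^\\s*([0-9.eE+-]+)\\s*(s|sec|min|h)\\s*$", x))[[1]]
    if (length(m) == 3L) {
      v <- as.numeric(m[2])
      return(switch(m[3], s = , sec = v / 60, min = v, h = v * 60))
    }
  }
  stop("config: cannot parse time value for ", what, ": '", x,
       "' (use a number in minutes or '<value> s|min|h')", call. = FALSE)
}

#' Save a trial configuration as YAML
#'
#' Writes the normalized configuration (all times in minutes) so that
#' `load_config(save_config(cfg, f))` reproduces `cfg` exactly.
#' @param cfg a [trial_config()].
#' @param path output YAML path.
#' @export
save_config <- function(cfg, path) {
  x <- list(
    population = list(means = lapply(unclass(cfg$population$means), identity),
                      omegas = as.list(cfg$population$omegas),
                      prop = cfg$population$prop, add = cfg$population$add),
    cohort = list(size = cfg$n, seed = cfg$seed,
                  demographics = list(age = cfg$demographics$age,
                                      weight = cfg$demographics$weight_kg,
                                      height = cfg$demographics$height_cm,
                                      sex = cfg$demographics$sex)),
    tci = list(mode = cfg$tci$mode, target = cfg$tci$target,
               control_interval = cfg$tci$control_interval,
               duration = cfg$tci$duration, max_rate = cfg$tci$max_rate),
    sensor = list(period = cfg$sensor$period, delay = cfg$sensor$delay,
                  start = cfg$sensor$start,
                  failure_probability = cfg$failure$probability,
                  failure_mode = cfg$failure$mode,
                  failure_magnitude = cfg$failure$magnitude),
    actuator = list(max_rate = cfg$actuator$max_rate,
                    min_rate_step = cfg$actuator$min_rate_step,
                    syringe_volume = cfg$actuator$syringe_volume,
                    low_reservoir_fraction = cfg$actuator$low_reservoir_fraction),
    arms = as.list(cfg$arms),
    output_grid = cfg$out_dt)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON record of a run: normalized config snapshot, seed, package version,
#' timestamp and an inventory of every output file with its MD5 checksum —
#' enough to verify that a rerun reproduced the outputs byte-identically.
#'
#' @param dir output directory whose files are inventoried.
#' @param cfg the [trial_config()] used.
#' @param seed the run seed.
#' @param path manifest path (default `manifest.json` inside `dir`).
#' @export
write_manifest <- function(dir, cfg, seed, path = file.path(dir, "manifest.json")) {
  files <- setdiff(list.files(dir), basename(path))
  sums <- tools::md5sum(file.path(dir, files))
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(cfg, tmp)
  manifest <- list(
    artifact = list(package = "isctsim",
                    version = as.character(utils::packageVersion("isctsim"))),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = yaml::read_yaml(tmp),
    outputs = lapply(seq_along(files), function(i)
      list(file = files[i], md5 = unname(sums[i]))))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
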