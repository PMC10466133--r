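#' Full trial configuration
#'
#' Assembles everything one in-silico trial needs: the population model, the
#' cohort recipe, the TCI objective, the sensor schedule and failure model,
#' the actuator limits and the arms to run. Normally built by
#' [load_config()]; exposed for programmatic use.
#'
#' @param population a [population_model()].
#' @param n cohort size.
#' @param seed integer seed for cohort generation and per-subject noise.
#' @param tci a [tci_config()].
#' @param sensor a [measurement_schedule()].
#' @param failure a [failure_model()].
#' @param actuator an [actuator_config()].
#' @param arms character subset of `c("open_loop", "closed_loop")`.
#' @param demographics shared cohort demographics (metadata).
#' @param out_dt output grid spacing, min.
#' @return Object of class `trial_config`.
#' @export
trial_config <- function(population, n, seed, tci, sensor,
                         failure = failure_model(0), actuator,
                         arms = c("open_loop", "closed_loop"),
                         demographics = list(age = 36, weight_kg = 70,
                                             height_cm = 170, sex = "female"),
                         out_dt = 0.1) {
  stopifnot(inherits(population, "population_model"),
            inherits(tci, "tci_config"),
            inherits(sensor, "measurement_schedule"),
            inherits(actuator, "actuator_config"))
  bad <- setdiff(arms, c("open_loop", "closed_loop"))
  if (length(bad)) stop("trial_config: unknown arm(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(population = population, n = as.integer(n),
                 seed = as.integer(seed), tci = tci, sensor = sensor,
                 failure = failure, actuator = actuator, arms = arms,
                 demographics = demographics, out_dt = out_dt),
            class = "trial_config")
}

# per-subject noise seeds derived from the trial seed; kept below 2^31
subject_seed <- function(seed, j) ((as.double(seed) + 104729 * j) %% 2147483629) + 1

#' Run a full in-silico trial
#'
#' Generates the virtual cohort, then runs the requested arms. The open-loop
#' arm computes one TCI schedule from the population model and administers
#' that identical schedule to every subject (the standard-pump scenario); the
#' closed-loop arm runs each subject through [run_closed_loop()] with its own
#' noise stream. The whole run is reproducible from `(config, seed)`.
#'
#' @param cfg a [trial_config()].
#' @return Object of class `trial_result`: list with `config`, `cohort`,
#'   `open_profile` (the population schedule), `reference` (the population
#'   model's own predicted trajectory under that schedule), and `arms`, a
#'   named list of `arm_result` objects (fields `arm`, `grid`, `C1` and `C4`
#'   time-by-subject matrices, `profiles`, `events`, `failed` subject ids).
#' @export
run_trial <- function(cfg) {
  stopifnot(inherits(cfg, "trial_config"))
  pop <- cfg$population
  cohort <- generate_cohort(pop, cfg$n, cfg$seed, cfg$demographics)
  grid <- seq(0, cfg$tci$duration, by = cfg$out_dt)
  open_profile <- tci_profile(pop$means, cfg$tci)
  reference <- propagate_exact(pop$means, open_profile, grid)

  arms <- list()
  if ("open_loop" %in% cfg$arms) {
    C1 <- matrix(NA_real_, length(grid), cfg$n)
    C4 <- matrix(NA_real_, length(grid), cfg$n)
    for (j in seq_len(cfg$n)) {
      tr <- propagate_exact(cohort$subjects[[j]]$params, open_profile, grid)
      C1[, j] <- tr$C1; C4[, j] <- tr$C4
    }
    arms$open_loop <- structure(
      list(arm = "open_loop", grid = grid, C1 = C1, C4 = C4,
           profiles = list(open_profile), events = NULL, failed = character(0)),
      class = "arm_result")
  }
  if ("closed_loop" %in% cfg$arms) {
    C1 <- matrix(NA_real_, length(grid), cfg$n)
    C4 <- matrix(NA_real_, length(grid), cfg$n)
    profiles <- vector("list", cfg$n)
    events <- vector("list", cfg$n)
    failed <- character(0)
    for (j in seq_len(cfg$n)) {
      res <- tryCatch(
        run_closed_loop(cohort$subjects[[j]], pop, cfg$tci$target, cfg$sensor,
                        cfg$actuator, cfg$tci$duration, fail = cfg$failure,
                        mode = cfg$tci$mode,
                        control_interval = cfg$tci$control_interval,
                        seed = subject_seed(cfg$seed, j), out_grid = grid),
        error = function(e) e)
      if (inherits(res, "error")) {
        failed <- c(failed, cohort$subjects[[j]]$subject_id)
        next
      }
      C1[, j] <- res$trajectory$C1; C4[, j] <- res$trajectory$C4
      profiles[[j]] <- res$infusion
      events[[j]] <- res$events
    }
    arms$closed_loop <- structure(
      list(arm = "closed_loop", grid = grid, C1 = C1, C4 = C4,
           profiles = profiles, events = events, failed = failed),
      class = "arm_result")
  }
  structure(list(config = cfg, cohort = cohort, open_profile = open_profile,
                 reference = reference, arms = arms),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat("<trial_result> n =", x$config$n, "| arms:",
      paste(names(x$arms), collapse = ", "), "\n")
  invisible(x)
}

#' Cohort concentration-time summary
#'
#' Pointwise median and empirical 2.5th/97.5th percentiles (the 95%
#' prediction interval) of a chosen concentration across the cohort, on the
#' arm's common time grid. Percentiles use the linear-interpolation
#' convention ([stats::quantile()] type 7).
#'
#' @param arm an `arm_result` from [run_trial()].
#' @param which `"C4"` (effect site) or `"C1"` (plasma).
#' @return Object of class `cohort_summary`: data frame with columns `time`,
#'   `lo95`, `median`, `hi95` (mg/L).
#' @export
summarize_ct_profiles <- function(arm, which = c("C4", "C1")) {
  which <- match.arg(which)
  m <- arm[[which]]
  m <- m[, colSums(is.na(m)) == 0, drop = FALSE]
  if (!ncol(m)) stop("summarize_ct_profiles: no subjects in arm", call. = FALSE)
  q <- t(apply(m, 1, quantile, probs = c(0.025, 0.5, 0.975), type = 7))
  out <- data.frame(time = arm$grid, lo95 = q[, 1], median = q[, 2], hi95 = q[, 3])
  attr(out, "which") <- which
  class(out) <- c("cohort_summary", "data.frame")
  out
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Accuracy metrics over the equilibrated window
#'
#' Quantifies how tightly an arm holds the cohort at the setpoint:
#' \itemize{
#' \item `band_area` — area of the 95% prediction interval,
#'   \eqn{\int (\mathrm{hi95} - \mathrm{lo95})\,dt}, over the window
#'   (mg/L x min); the headline comparison between arms.
#' \item `within_10pct_fraction` — fraction of subjects whose concentration
#'   stays within 10% of the target throughout the window.
#' \item `max_rel_deviation` — largest relative deviation of any subject
#'   from the population-model prediction over the window,
#'   \eqn{\max_j \max_t |C_j(t) - C_{pop}(t)| / C_{pop}(t)}.
#' \item `flagged_subjects` — ids of subjects whose concentration deviates
#'   from the target by more than `dose_threshold` anywhere in the window
#'   (potential under-/over-dosing).
#' }
#'
#' @param arm an `arm_result`.
#' @param target setpoint, mg/L (`> 0` for the relative metrics).
#' @param window numeric length-2 time window, min; default the second half
#'   of the trial (the equilibrated portion).
#' @param reference population prediction: data frame with `time` and the
#'   chosen concentration column (e.g. the `reference` field of a
#'   `trial_result`); required for `max_rel_deviation`.
#' @param which concentration to assess, `"C4"` or `"C1"`.
#' @param subject_ids optional ids for flagging (defaults to column index).
#' @param dose_threshold under/over-dosing flag threshold (default 0.2).
#' @return list with the four metrics plus the `summary` used.
#' @export
accuracy_metrics <- function(arm, target, window = NULL, reference = NULL,
                             which = c("C4", "C1"), subject_ids = NULL,
                             dose_threshold = 0.2) {
  which <- match.arg(which)
  if (target <= 0) stop("accuracy_metrics: target must be > 0", call. = FALSE)
  grid <- arm$grid
  if (is.null(window)) window <- c(max(grid) / 2, max(grid))
  sel <- grid >= window[1] & grid <= window[2]
  if (!any(sel)) stop("accuracy_metrics: window outside the grid", call. = FALSE)
  s <- summarize_ct_profiles(arm, which)
  band_area <- trapz(grid[sel], (s$hi95 - s$lo95)[sel])

  m <- arm[[which]][sel, , drop = FALSE]
  ok_sub <- colSums(is.na(m)) == 0
  within <- apply(abs(m[, ok_sub, drop = FALSE] - target) <= 0.1 * target, 2, all)
  ids <- subject_ids %||% sprintf("S%04d", seq_len(ncol(arm[[which]])))
  dev <- apply(abs(m[, ok_sub, drop = FALSE] - target) > dose_threshold * target, 2, any)
  flagged <- ids[ok_sub][dev]

  max_rel <- NA_real_
  if (!is.null(reference)) {
    cpop <- approx(reference$time, reference[[which]], xout = grid[sel])$y
    rel <- abs(m[, ok_sub, drop = FALSE] - cpop) / cpop
    max_rel <- max(rel)
  }
  list(band_area = band_area,
       within_10pct_fraction = mean(within),
       max_rel_deviation = max_rel,
       flagged_subjects = flagged,
       summary = s)
}

#' Write a cohort summary as CSV
#' @param summary a `cohort_summary`.
#' @param path CSV path.
#' @export
write_summary_csv <- function(summary, path) {
  write.csv(as.data.frame(summary), path, row.names = FALSE)
  invisible(path)
}
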