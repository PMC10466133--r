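#' Sensor measurement schedule
#'
#' Timing of plasma-concentration measurements: `period` is the time between
#' consecutive samples, `delay` the time until a sample's value becomes
#' available to the controller, `start` the first sample time. Arguments are
#' taken in seconds (the natural unit for sensor hardware) and stored
#' internally in minutes.
#'
#' @param period_s time between consecutive samples, s (`> 0`).
#' @param delay_s availability lag tau, s (`>= 0`).
#' @param start_s first sample time, s (default one period).
#' @return Object of class `measurement_schedule` with fields in minutes.
#' @examples
#' measurement_schedule(period_s = 30, delay_s = 15)
#' @export
measurement_schedule <- function(period_s, delay_s = 0, start_s = period_s) {
  if (period_s <= 0) stop("measurement_schedule: period must be > 0", call. = FALSE)
  if (delay_s < 0) stop("measurement_schedule: delay must be >= 0", call. = FALSE)
  structure(list(period = period_s / 60, delay = delay_s / 60,
                 start = start_s / 60), class = "measurement_schedule")
}

#' Sensor failure model
#'
#' Occasional out-of-distribution readings: each sample independently fails
#' with probability `probability`; a failed sample's value is replaced by a
#' `spike` (multiplied by `magnitude`), a `dropout` (value 0) or a `stuck`
#' reading (previous value repeated).
#'
#' @param probability per-sample failure chance in `[0, 1]`.
#' @param mode failure type.
#' @param magnitude spike multiplier (only used for `mode = "spike"`).
#' @return Object of class `failure_model`.
#' @export
failure_model <- function(probability = 0, mode = c("spike", "dropout", "stuck"),
                          magnitude = 5) {
  if (probability < 0 || probability > 1)
    stop("failure_model: probability must be in [0, 1]", call. = FALSE)
  structure(list(probability = probability, mode = match.arg(mode),
                 magnitude = magnitude), class = "failure_model")
}

# sample times of a schedule within [0, t_end]
schedule_times <- function(sched, t_end) {
  if (sched$start > t_end) return(numeric(0))
  seq(sched$start, t_end, by = sched$period)
}

# corrupt one or more true concentrations into sensor readings; draws noise
# (and failures) from the current RNG stream in order
corrupt_values <- function(C, pop, fail, prev = NA_real_) {
  y <- apply_residual_error(C, pop)
  is_fail <- rep(FALSE, length(C))
  if (fail$probability > 0) {
    is_fail <- runif(length(C)) < fail$probability
    if (any(is_fail)) {
      y[is_fail] <- switch(fail$mode,
        spike = y[is_fail] * fail$magnitude,
        dropout = 0,
        stuck = {
          for (i in which(is_fail)) y[i] <- if (i > 1) y[i - 1] else prev
          y[is_fail]
        })
    }
  }
  list(value = y, is_failure = is_fail)
}

#' Emulate sensor measurements along a trajectory
#'
#' Interpolates the true plasma concentration `C1` at each scheduled sample
#' time, corrupts it with the population residual-error model
#' ([apply_residual_error()]), optionally injects out-of-distribution
#' failures, and stamps each reading with the time at which it becomes
#' available (`sample_time + delay`).
#'
#' @param traj a `pk_trajectory` (or data frame with `time` and `C1`).
#' @param pop a [population_model()] (supplies `prop` / `add`).
#' @param sched a [measurement_schedule()].
#' @param fail a [failure_model()]; default none.
#' @return Object of class `measurement_stream`: data frame with columns
#'   `sample_time`, `available_time` (min), `value` (mg/L), `is_failure`,
#'   ordered by `available_time`.
#' @export
sample_measurements <- function(traj, pop, sched, fail = failure_model(0)) {
  t_end <- max(traj$time)
  tn <- schedule_times(sched, t_end)
  if (!length(tn))
    stop("sample_measurements: schedule does not overlap the trajectory span",
         call. = FALSE)
  C <- approx(traj$time, traj$C1, xout = tn)$y
  cr <- corrupt_values(C, pop, fail)
  out <- data.frame(sample_time = tn, available_time = tn + sched$delay,
                    value = cr$value, is_failure = cr$is_failure)
  out <- out[order(out$available_time), ]
  rownames(out) <- NULL
  class(out) <- c("measurement_stream", "data.frame")
  out
}

#' Export a measurement stream as CSV (times in seconds)
#' @param ms a `measurement_stream`.
#' @param path CSV path.
#' @export
write_measurements_csv <- function(ms, path) {
  df <- data.frame(sample_time_s = ms$sample_time * 60,
                   available_time_s = ms$available_time * 60,
                   value_mg_per_L = ms$value, is_failure = ms$is_failure)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
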