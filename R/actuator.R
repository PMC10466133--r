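#' Actuator (pump) configuration
#'
#' Device-side delivery constraints: the physiological/device rate ceiling,
#' optional rate quantization, syringe capacity and the low-reservoir alarm
#' threshold. There is no universal physiological maximum rate, so `max_rate`
#' has no default and must be supplied.
#'
#' @param max_rate maximum deliverable rate, mg/min (`> 0`).
#' @param min_rate_step rate quantization, mg/min (0 = continuous pump).
#' @param syringe_volume drug available in the syringe, mg (may be `Inf`).
#' @param low_reservoir_fraction alarm threshold as a fraction of
#'   `syringe_volume`, in `[0, 1)`.
#' @return Object of class `actuator_config`.
#' @export
actuator_config <- function(max_rate, min_rate_step = 0,
                            syringe_volume = Inf, low_reservoir_fraction = 0.1) {
  if (max_rate <= 0) stop("actuator_config: max_rate must be > 0", call. = FALSE)
  if (min_rate_step < 0) stop("actuator_config: min_rate_step must be >= 0", call. = FALSE)
  if (low_reservoir_fraction < 0 || low_reservoir_fraction >= 1)
    stop("actuator_config: low_reservoir_fraction must be in [0, 1)", call. = FALSE)
  structure(list(max_rate = max_rate, min_rate_step = min_rate_step,
                 syringe_volume = syringe_volume,
                 low_reservoir_fraction = low_reservoir_fraction),
            class = "actuator_config")
}

#' Constrain a requested delivery rate to what the pump can deliver
#'
#' Quantizes and clips the controller's requested rate to `[0, max_rate]` and
#' raises alarms: `SATURATED` when the request was clipped from above,
#' `NEGATIVE_REQUEST` when the controller asked for a negative rate (a
#' contract breach, treated as 0), `LOW_RESERVOIR` when the remaining drug is
#' below the alarm fraction and `EMPTY` (rate forced to 0) when the syringe
#' is exhausted.
#'
#' @param requested requested rate, mg/min (finite).
#' @param cfg an [actuator_config()].
#' @param reservoir remaining drug, mg.
#' @return list with `rate` (the actual deliverable rate, mg/min) and
#'   `alarms` (character vector, possibly empty).
#' @export
constrain_rate <- function(requested, cfg, reservoir = cfg$syringe_volume) {
  if (!is.finite(requested)) stop("constrain_rate: requested rate must be finite", call. = FALSE)
  alarms <- character(0)
  r <- requested
  if (r < 0) { alarms <- c(alarms, "NEGATIVE_REQUEST"); r <- 0 }
  if (cfg$min_rate_step > 0) r <- round(r / cfg$min_rate_step) * cfg$min_rate_step
  if (r > cfg$max_rate) { alarms <- c(alarms, "SATURATED"); r <- cfg$max_rate }
  if (reservoir <= 0) { alarms <- c(alarms, "EMPTY"); r <- 0 }
  else if (is.finite(cfg$syringe_volume) &&
           reservoir / cfg$syringe_volume < cfg$low_reservoir_fraction)
    alarms <- c(alarms, "LOW_RESERVOIR")
  list(rate = r, alarms = alarms)
}

#' Deplete the reservoir over a delivery interval
#'
#' @param reservoir remaining drug, mg.
#' @param rate actual delivery rate, mg/min.
#' @param dt interval length, min (`>= 0`).
#' @return list with `reservoir` (updated, floored at 0) and `delivered`
#'   (amount actually delivered over the interval, truncated when the
#'   reservoir runs out).
#' @export
deplete <- function(reservoir, rate, dt) {
  if (dt < 0) stop("deplete: dt must be >= 0", call. = FALSE)
  want <- rate * dt
  delivered <- min(want, max(reservoir, 0))
  list(reservoir = max(reservoir - want, 0), delivered = delivered)
}
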