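#' Target-controlled-infusion configuration
#'
#' @param mode `"plasma"` or `"effect_site"`: which concentration the
#'   algorithm drives to the setpoint.
#' @param target setpoint concentration, mg/L (`>= 0`).
#' @param control_interval time between rate updates, min (default 10 s).
#' @param duration schedule length, min.
#' @param max_rate pump ceiling, mg/min.
#' @return Object of class `tci_config`.
#' @export
tci_config <- function(mode = c("effect_site", "plasma"), target,
                       control_interval = 1 / 6, duration, max_rate) {
  mode <- match.arg(mode)
  if (target < 0) stop("tci_config: target must be >= 0", call. = FALSE)
  if (control_interval <= 0) stop("tci_config: control_interval must be > 0", call. = FALSE)
  if (duration <= control_interval) stop("tci_config: duration too short", call. = FALSE)
  if (max_rate <= 0) stop("tci_config: max_rate must be > 0", call. = FALSE)
  structure(list(mode = mode, target = target,
                 control_interval = control_interval,
                 duration = duration, max_rate = max_rate),
            class = "tci_config")
}

# One-step rate law, shared between open-loop TCI and the personalized
# controller (which calls it with the individualized model and its own
# predicted state).
#
# plasma mode: the one-interval prediction C1(t+dt) is affine in the rate,
#   C1 = a + b*U, so the rate that lands exactly on target is (target - a)/b,
#   clipped to [0, max_rate] (rate 0 while the prediction exceeds target).
# effect-site mode: predicted peak of C4 (rate U over the next interval, then
#   zero) is monotone increasing in U; the rate is chosen by root finding so
#   the peak equals the target — the schedule therefore rises at full rate
#   while the target is unreachable in one step, trims the final pulse so the
#   peak touches the target exactly, and settles into maintenance.
plan_rate <- function(M, V1, x, mode, target, dt, max_rate,
                      horizon, peak_dt = 0.02) {
  if (target <= 0) return(list(rate = 0, clipped = FALSE))
  if (mode == "plasma") {
    a <- cpp_c1_at(M, x, c(0, dt), 0, dt, V1)
    b <- cpp_c1_at(M, numeric(4), c(0, dt), 1, dt, V1)
    u <- (target - a) / b
    list(rate = min(max(u, 0), max_rate), clipped = u > max_rate)
  } else {
    g <- function(u) cpp_peak_c4(M, x, u, dt, horizon, peak_dt)
    if (g(0) >= target) return(list(rate = 0, clipped = FALSE))
    if (g(max_rate) <= target) return(list(rate = max_rate, clipped = TRUE))
    u <- uniroot(function(u) g(u) - target, c(0, max_rate),
                 tol = 1e-6 * max(1, target))$root
    list(rate = u, clipped = FALSE)
  }
}

# effect-site planning horizon: several equilibration half-lives past the pulse
plan_horizon <- function(ke0, dt) dt + 5 * log(2) / ke0

# iterate the one-step law under the model itself (certainty equivalence):
# the open-loop schedule for a subject described exactly by `params`
tci_profile <- function(params, cfg, init = c(0, 0, 0, 0)) {
  rc <- derive_rate_constants(params)
  M <- pk_matrix(rc)
  dt <- cfg$control_interval
  steps <- ceiling(cfg$duration / dt - 1e-9)
  t0 <- (seq_len(steps) - 1L) * dt
  rates <- numeric(steps)
  clipped <- FALSE
  x <- as.numeric(init)
  horizon <- plan_horizon(params$ke0, dt)
  pred <- matrix(0, nrow = steps, ncol = 4)
  for (i in seq_len(steps)) {
    pl <- plan_rate(M, params$V1, x, cfg$mode, cfg$target, dt, cfg$max_rate, horizon)
    rates[i] <- pl$rate
    clipped <- clipped || pl$clipped
    x <- cpp_pw_states(M, x, c(0, dt), pl$rate, dt)[, 1]
    pred[i, ] <- x
  }
  prof <- infusion_profile(t0, rates, end = cfg$duration)
  final <- if (cfg$mode == "plasma") pred[steps, 1] / params$V1 else pred[steps, 4]
  attr(prof, "saturated") <- clipped && final < 0.99 * cfg$target
  attr(prof, "predicted") <- data.frame(time = t0 + dt,
                                        C1 = pred[, 1] / params$V1,
                                        C4 = pred[, 4])
  prof
}

#' Open-loop TCI schedule targeting a plasma concentration
#'
#' Computes the piecewise-constant delivery schedule that drives the
#' model-predicted plasma concentration `C1` to the setpoint and holds it
#' there, using only the supplied (population) model. At each control
#' interval the rate landing the one-step prediction exactly on target is
#' applied, clipped to `[0, max_rate]`; while the prediction exceeds the
#' target the rate is zero.
#'
#' @param params a [pk_params()] object (the population model's parameters).
#' @param cfg a [tci_config()] with `mode = "plasma"`.
#' @return An [infusion_profile()] with attributes `predicted` (the model's
#'   own `C1`/`C4` at the control grid) and `saturated` (`TRUE` when the
#'   target could not be attained under `max_rate`).
#' @export
plasma_targeting_rates <- function(params, cfg) {
  if (!inherits(params, "pk_params")) params <- do.call(pk_params, as.list(params))
  stopifnot(inherits(cfg, "tci_config"))
  if (cfg$mode != "plasma") stop("plasma_targeting_rates: cfg$mode must be 'plasma'", call. = FALSE)
  tci_profile(params, cfg)
}

#' Open-loop TCI schedule targeting an effect-site concentration
#'
#' Computes the delivery schedule that brings the model-predicted effect-site
#' concentration `C4` to the setpoint without overshoot and holds it there:
#' full-rate loading while the target is out of one-step reach, a trimmed
#' final pulse whose predicted `C4` peak touches the target exactly, then
#' maintenance rates that keep the predicted peak pinned at the target.
#'
#' @inheritParams plasma_targeting_rates
#' @param cfg a [tci_config()] with `mode = "effect_site"`.
#' @return As [plasma_targeting_rates()].
#' @export
effect_site_targeting_rates <- function(params, cfg) {
  if (!inherits(params, "pk_params")) params <- do.call(pk_params, as.list(params))
  stopifnot(inherits(cfg, "tci_config"))
  if (cfg$mode != "effect_site") stop("effect_site_targeting_rates: cfg$mode must be 'effect_site'", call. = FALSE)
  tci_profile(params, cfg)
}
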