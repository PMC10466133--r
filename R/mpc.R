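#' Controller state for the personalized closed-loop controller
#'
#' Bundles everything the controller knows at a point in time: the current
#' MAP estimate of the subject's random effects (`eta_hat`, initialized at
#' the population prior mode 0), the measurements received so far (respecting
#' availability times), the infusion administered so far, and the control
#' objective.
#'
#' @param target setpoint, mg/L.
#' @param mode `"effect_site"` or `"plasma"`.
#' @param control_interval rate-update interval, min.
#' @param pop a [population_model()] (defines which parameters are free:
#'   those with `omega > 0`).
#' @return Object of class `controller_state`.
#' @export
controller_state <- function(target, mode = c("effect_site", "plasma"),
                             control_interval, pop) {
  mode <- match.arg(mode)
  structure(list(
    eta_hat = setNames(rep(0, length(pop$omegas)), names(pop$omegas)),
    buffer = data.frame(sample_time = numeric(0), available_time = numeric(0),
                        value = numeric(0), is_failure = logical(0)),
    infusion_bounds = 0, infusion_rates = numeric(0),
    target = target, mode = mode, control_interval = control_interval),
    class = "controller_state")
}

# measurement-time plasma predictions for a candidate eta, given the infusion
# administered so far
predict_c1 <- function(pop, eta, bounds, rates, times) {
  pv <- unlist(pop$means[.pk_param_names]) * exp(eta)
  params <- do.call(pk_params, as.list(pv))
  rc <- derive_rate_constants(params)
  cpp_c1_at(pk_matrix(rc), numeric(4), bounds, rates, times, params$V1)
}

#' MAP (maximum a posteriori) update of the individual random effects
#'
#' Minimizes the penalized weighted least-squares objective
#' \deqn{\sum_n \frac{(Y_n - C_1(t_n; PAR\,e^{\eta}))^2}{prop^2 C_1^2 + add^2}
#'       + \sum_k \frac{\eta_k^2}{\omega_k^2}}
#' over the random effects of the parameters with `omega > 0`, i.e. the
#' posterior mode under the log-normal population prior and the combined
#' residual-error likelihood. Optimization is quasi-Newton (L-BFGS-B) warm
#' started from the previous estimate and bounded at `|eta_k| <= 5 omega_k`
#' so outlier readings cannot drive the estimate off to infinity. When both
#' residual terms are zero the fit is unweighted least squares. On optimizer
#' failure the previous estimate is retained with a warning.
#'
#' @param pop a [population_model()].
#' @param state a [controller_state()] whose buffer holds the available
#'   measurements.
#' @param include_flagged include failure-flagged readings in the likelihood
#'   (default `TRUE`; robustness experiments may exclude them).
#' @return the state with `eta_hat` updated.
#' @export
bayesian_update <- function(pop, state, include_flagged = TRUE) {
  free <- which(pop$omegas > 0)
  meas <- state$buffer
  if (!include_flagged) meas <- meas[!meas$is_failure, , drop = FALSE]
  if (!length(free) || !nrow(meas)) return(state)

  omega <- pop$omegas[free]
  bounds <- state$infusion_bounds
  rates <- state$infusion_rates
  unweighted <- pop$prop == 0 && pop$add == 0
  cost <- function(ef) {
    eta <- state$eta_hat
    eta[free] <- ef
    c1 <- predict_c1(pop, eta, bounds, rates, meas$sample_time)
    w <- if (unweighted) 1 else pop$prop^2 * c1^2 + pop$add^2
    sum((meas$value - c1)^2 / w) + sum(ef^2 / omega^2)
  }
  fit <- tryCatch(
    optim(state$eta_hat[free], cost, method = "L-BFGS-B",
          lower = -5 * omega, upper = 5 * omega,
          control = list(maxit = 100, factr = 1e7)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("bayesian_update: optimizer failed; keeping previous estimate")
    return(state)
  }
  state$eta_hat[free] <- fit$par
  state
}

#' Next delivery rate from the personalized model
#'
#' Applies the same one-step rate law as the open-loop TCI algorithm, but to
#' the individualized model `PAR * exp(eta_hat)` and the controller's own
#' reconstruction of the current compartment state under that model. With
#' `eta_hat = 0` this reproduces the open-loop TCI rate exactly.
#'
#' @param pop a [population_model()].
#' @param state a [controller_state()].
#' @param now current time, min.
#' @param max_rate actuator ceiling, mg/min.
#' @return rate, mg/min.
#' @export
mpc_rate <- function(pop, state, now, max_rate) {
  pv <- unlist(pop$means[.pk_param_names]) * exp(state$eta_hat)
  params <- do.call(pk_params, as.list(pv))
  rc <- derive_rate_constants(params)
  M <- pk_matrix(rc)
  x_hat <- if (now > 0)
    cpp_pw_states(M, numeric(4), c(state$infusion_bounds, now),
                  c(state$infusion_rates, 0), now)[, 1]
  else numeric(4)
  pl <- plan_rate(M, params$V1, x_hat, state$mode, state$target,
                  state$control_interval, max_rate,
                  plan_horizon(params$ke0, state$control_interval))
  pl$rate
}

#' Run one subject through the closed loop
#'
#' Event-driven simulation of the full loop of sensor, estimator, rate law
#' and actuator against a virtual subject: the subject's true dynamics are
#' propagated exactly with the subject's own parameters; scheduled sensor
#' samples of the true plasma concentration are corrupted with the residual
#' error model and become usable only at `sample_time + delay`, at which
#' point the MAP estimate is refreshed and the rate replanned; rates are also
#' replanned at every control interval, and every commanded rate passes
#' through the actuator constraints (with reservoir depletion and alarms).
#'
#' @param subject a [sample_subject()] result (the ground-truth subject).
#' @param pop the [population_model()] the controller believes in.
#' @param target setpoint, mg/L.
#' @param sched a [measurement_schedule()].
#' @param act an [actuator_config()].
#' @param duration trial length, min.
#' @param fail a [failure_model()]; default none.
#' @param mode target mode.
#' @param control_interval rate-update interval, min; defaults to the
#'   measurement period.
#' @param seed optional integer seed making the run bit-reproducible.
#' @param estimator estimation strategy, signature `(pop, state,
#'   include_flagged)`; default [bayesian_update()].
#' @param include_flagged passed to the estimator.
#' @param out_grid output time grid, min; default every 0.1 min.
#' @return list with `trajectory` (true states on `out_grid`), `infusion`
#'   (the administered [infusion_profile()]), `measurements`
#'   (`measurement_stream`), `events` (event log data frame), `eta_hat`
#'   (final estimate) and `alarms`.
#' @export
run_closed_loop <- function(subject, pop, target, sched, act, duration,
                            fail = failure_model(0),
                            mode = c("effect_site", "plasma"),
                            control_interval = sched$period, seed = NULL,
                            estimator = bayesian_update, include_flagged = TRUE,
                            out_grid = seq(0, duration, by = 0.1)) {
  mode <- match.arg(mode)
  runner <- function() {
    rc_true <- derive_rate_constants(subject$params)
    M_true <- pk_matrix(rc_true)
    st <- controller_state(target, mode, control_interval, pop)

    control_t <- seq(0, duration, by = control_interval)
    sample_t <- schedule_times(sched, duration)
    sample_t <- sample_t[sample_t < duration]
    avail_t <- sample_t + sched$delay
    events_t <- sort(unique(round(c(control_t, sample_t,
                                    avail_t[avail_t < duration], duration), 10)))
    is_control <- events_t %in% round(control_t, 10)
    is_sample <- events_t %in% round(sample_t, 10)

    x <- numeric(4)
    reservoir <- act$syringe_volume
    pending <- NULL
    rate <- 0
    prev_y <- NA_real_
    log <- list(); li <- 0
    logev <- function(time, event, value, detail = "") {
      li <<- li + 1
      log[[li]] <<- data.frame(time = time, event = event, value = value,
                               detail = detail)
    }
    meas_rows <- list()

    for (i in seq_along(events_t)) {
      t_now <- events_t[i]
      if (i == length(events_t)) break
      dt <- events_t[i + 1] - t_now

      if (is_sample[i]) {
        cr <- corrupt_values(x[1] / subject$params$V1, pop, fail, prev = prev_y)
        prev_y <- cr$value
        row <- data.frame(sample_time = t_now,
                          available_time = t_now + sched$delay,
                          value = cr$value, is_failure = cr$is_failure)
        pending <- rbind(pending, row)
        meas_rows[[length(meas_rows) + 1]] <- row
        logev(t_now, "measure", cr$value,
              if (cr$is_failure) "FAILURE" else "")
      }

      updated <- FALSE
      if (!is.null(pending) && any(ok <- pending$available_time <= t_now + 1e-9)) {
        st$buffer <- rbind(st$buffer, pending[ok, , drop = FALSE])
        pending <- pending[!ok, , drop = FALSE]
        eta_before <- st$eta_hat
        st <- estimator(pop, st, include_flagged)
        # replan off the control grid only when the estimate actually moved
        updated <- any(st$eta_hat != eta_before)
        logev(t_now, "update", sqrt(sum(st$eta_hat^2)),
              paste0("n_meas=", nrow(st$buffer)))
      }

      if (is_control[i] || updated) {
        requested <- mpc_rate(pop, st, t_now, act$max_rate)
        con <- constrain_rate(requested, act, reservoir)
        if (con$rate != rate || i == 1) {
          rate <- con$rate
          logev(t_now, "rate_change", rate,
                paste0("last_avail=",
                       if (nrow(st$buffer)) max(st$buffer$available_time) else -1))
        }
        for (al in con$alarms) logev(t_now, "alarm", NA_real_, al)
      }

      # deliver over [t_now, t_now + dt); truncate at reservoir exhaustion
      dep <- deplete(reservoir, rate, dt)
      dt_active <- if (rate > 0) dep$delivered / rate else dt
      if (dt_active < dt - 1e-12) {
        x <- cpp_pw_states(M_true, x, c(0, dt_active, dt), c(rate, 0), dt)[, 1]
        logev(t_now + dt_active, "alarm", NA_real_, "EMPTY")
        applied <- c(rate, 0)
      } else {
        x <- cpp_pw_states(M_true, x, c(0, dt), rate, dt)[, 1]
        applied <- rate
      }
      reservoir <- dep$reservoir
      # record administered segment(s) on the controller's infusion history
      if (length(applied) == 2) {
        st$infusion_bounds <- c(st$infusion_bounds, t_now + dt_active, t_now + dt)
        st$infusion_rates <- c(st$infusion_rates, applied)
      } else {
        st$infusion_bounds <- c(st$infusion_bounds, t_now + dt)
        st$infusion_rates <- c(st$infusion_rates, applied)
      }
    }

    prof_t <- st$infusion_bounds[-length(st$infusion_bounds)]
    keep <- c(TRUE, diff(st$infusion_rates) != 0)
    prof <- infusion_profile(prof_t[keep], st$infusion_rates[keep], end = duration)
    traj <- propagate_exact(subject$params, prof, out_grid)
    events <- if (li) do.call(rbind, log) else
      data.frame(time = numeric(0), event = character(0),
                 value = numeric(0), detail = character(0))
    ms <- if (length(meas_rows)) {
      m <- do.call(rbind, meas_rows)
      m <- m[order(m$available_time), ]
      rownames(m) <- NULL
      class(m) <- c("measurement_stream", "data.frame")
      m
    } else NULL
    list(trajectory = traj, infusion = prof, measurements = ms,
         events = events, eta_hat = st$eta_hat,
         alarms = unique(events$detail[events$event == "alarm"]))
  }
  if (is.null(seed)) runner() else withr::with_seed(as.integer(seed), runner())
}
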