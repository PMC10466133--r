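# build a controller state with a given measurement history and infusion record
make_state <- function(pop, bounds, rates, t_meas, y, mode = "effect_site",
                       target = 6, dt = 0.5) {
  st <- controller_state(target, mode, dt, pop)
  st$infusion_bounds <- bounds
  st$infusion_rates <- rates
  st$buffer <- data.frame(sample_time = t_meas, available_time = t_meas,
                          value = y, is_failure = FALSE)
  st
}

test_that("with no measurements the estimate stays at the prior mode", {
  pop <- ref_pop()
  st <- controller_state(6, "effect_site", 0.5, pop)
  st2 <- bayesian_update(pop, st)
  expect_identical(st2$eta_hat, st$eta_hat)
  expect_true(all(st2$eta_hat == 0))
})

test_that("noiseless measurements recover a known subject's random effects", {
  pop <- population_model(ref_params(),
                          omegas = c(CL = 10, V1 = 10, V2 = 10),
                          prop = 0, add = 0)
  eta_true <- c(CL = 0.3, V1 = -0.2, V2 = 0.15, V3 = 0, Q2 = 0, Q3 = 0, ke0 = 0)
  subj <- isctsim:::subject_from_etas(pop, eta_true, "truth")
  bounds <- c(0, 2, 10, 20)
  rates <- c(100, 0, 20)
  t_meas <- seq(1, 20, length.out = 20)
  prof <- infusion_profile(bounds[-4], rates, end = 20)
  y <- isctsim:::propagate_exact(subj$params, prof, t_meas)$C1
  st <- make_state(pop, bounds, rates, t_meas, y)
  st <- bayesian_update(pop, st)
  free <- c("CL", "V1", "V2")
  expect_lt(max(abs(st$eta_hat[free] - eta_true[free]) / abs(eta_true[free])), 0.02)
})

test_that("an overwhelming additive error term makes the prior dominate", {
  pop <- population_model(ref_params(), omegas = c(CL = 0.5, V1 = 0.8),
                          prop = 0, add = 1e6)
  st <- make_state(pop, c(0, 1, 5), c(100, 10), t_meas = 4, y = 12)
  st <- bayesian_update(pop, st)
  expect_lt(max(abs(st$eta_hat)), 1e-4)
})

test_that("with eta_hat at the prior mode the controller reproduces the open-loop TCI rate", {
  pop <- ref_pop(prop = 0, add = 0)
  cfg <- tci_config("effect_site", 6, control_interval = 0.5, duration = 10,
                    max_rate = 200)
  prof <- effect_site_targeting_rates(pop$means, cfg)
  # replay the open-loop history through mpc_rate step by step
  st <- controller_state(6, "effect_site", 0.5, pop)
  for (i in seq_len(6)) {
    now <- (i - 1) * 0.5
    r <- mpc_rate(pop, st, now, max_rate = 200)
    expect_equal(r, rate_at(prof, now + 0.1), tolerance = 1e-6)
    st$infusion_bounds <- c(st$infusion_bounds, now + 0.5)
    st$infusion_rates <- c(st$infusion_rates, r)
  }
})

test_that("a personalized steady state demands a clearance-proportional maintenance rate", {
  p <- small_params()
  p2 <- do.call(pk_params, modifyList(as.list(unclass(p)), list(CL = 2 * p$CL)))
  late_rate <- function(params) {
    cfg <- tci_config("plasma", 2, control_interval = 0.5, duration = 240,
                      max_rate = 500)
    prof <- plasma_targeting_rates(params, cfg)
    mean(prof$rates[prof$times > 200])
  }
  r1 <- late_rate(p)
  r2 <- late_rate(p2)
  expect_equal(r1, p$CL * 2, tolerance = 0.01)   # U = CL * C_target
  expect_equal(r2 / r1, 2, tolerance = 0.01)
})

test_that("a prediction already above target requests zero rate", {
  pop <- ref_pop(prop = 0, add = 0)
  st <- controller_state(1, "effect_site", 0.5, pop)
  st$infusion_bounds <- c(0, 1)
  st$infusion_rates <- 500            # huge loading: prediction far above 1 mg/L
  expect_equal(mpc_rate(pop, st, 1, max_rate = 200), 0)
})

test_that("without usable information the closed loop equals the open loop", {
  pop <- ref_pop(omega_scale = 0, prop = 0, add = 0)   # no variability, no noise
  coh <- generate_cohort(pop, 1, seed = 2)
  act <- actuator_config(max_rate = 200)
  sched <- measurement_schedule(30, 15)
  res <- run_closed_loop(coh$subjects[[1]], pop, 6, sched, act, duration = 10,
                         control_interval = 1 / 6, seed = 2)
  cfg <- tci_config("effect_site", 6, control_interval = 1 / 6, duration = 10,
                    max_rate = 200)
  open <- effect_site_targeting_rates(pop$means, cfg)
  g <- seq(0, 10, 0.1)
  tr_open <- simulate_pk(pop$means, open, g)
  expect_equal(res$trajectory$C4, tr_open$C4, tolerance = 1e-6)

  # same result when measurements exist but never become available in time
  pop2 <- ref_pop(prop = 0, add = 0)
  coh2 <- generate_cohort(pop2, 1, seed = 3)
  late <- measurement_schedule(30, delay_s = 3600)
  res2 <- run_closed_loop(coh2$subjects[[1]], pop2, 6, late, act, duration = 10,
                          control_interval = 1 / 6, seed = 3)
  tr_open2 <- isctsim:::propagate_exact(coh2$subjects[[1]]$params, open, g)
  expect_equal(res2$trajectory$C4, tr_open2$C4, tolerance = 1e-8)
})

test_that("personalization steers a mis-specified subject onto the target", {
  pop <- population_model(ref_params(), omegas = c(CL = 0.5, V1 = 0.8),
                          prop = 0, add = 0)
  eta_true <- c(CL = log(1.5), V1 = 0.3, V2 = 0, V3 = 0, Q2 = 0, Q3 = 0, ke0 = 0)
  subj <- isctsim:::subject_from_etas(pop, eta_true, "S1")
  sched <- measurement_schedule(period_s = 10, delay_s = 0)
  act <- actuator_config(max_rate = 200)
  res <- run_closed_loop(subj, pop, 6, sched, act, duration = 15, seed = 10)
  tr <- res$trajectory
  expect_lt(abs(mean(tr$C4[tr$time >= 11.25]) - 6) / 6, 0.02)
})

test_that("closed-loop runs are reproducible from their seed", {
  pop <- ref_pop()
  coh <- generate_cohort(pop, 1, seed = 5)
  act <- actuator_config(max_rate = 200)
  sched <- measurement_schedule(30, 15)
  r1 <- run_closed_loop(coh$subjects[[1]], pop, 6, sched, act, 8, seed = 123)
  r2 <- run_closed_loop(coh$subjects[[1]], pop, 6, sched, act, 8, seed = 123)
  expect_identical(r1$infusion, r2$infusion)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$measurements, r2$measurements)
})

test_that("no rate uses a measurement before its availability time", {
  pop <- ref_pop()
  coh <- generate_cohort(pop, 1, seed = 11)
  act <- actuator_config(max_rate = 200)
  res <- run_closed_loop(coh$subjects[[1]], pop, 6, measurement_schedule(30, 15),
                         act, duration = 8, seed = 11)
  ev <- res$events
  rc <- ev[ev$event == "rate_change", ]
  last_avail <- as.numeric(sub("last_avail=", "", rc$detail))
  expect_true(all(last_avail <= rc$time + 1e-9))
  # every measurement is used only after its delay
  upd <- ev[ev$event == "update", ]
  ms <- res$measurements
  for (t in upd$time)
    expect_true(all(ms$available_time[ms$available_time <= t + 1e-9] <= t + 1e-9))
  expect_true(all(ms$available_time - ms$sample_time == 15 / 60))
})
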