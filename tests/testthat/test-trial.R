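tiny_config <- function(n = 2, omega_scale = 1, prop = 0.19, add = 0.02,
                        duration = 6, arms = c("open_loop", "closed_loop"),
                        seed = 42) {
  trial_config(
    population = ref_pop(omega_scale, prop, add),
    n = n, seed = seed,
    tci = tci_config("effect_site", 6, control_interval = 1 / 6,
                     duration = duration, max_rate = 200),
    sensor = measurement_schedule(30, 15),
    actuator = actuator_config(max_rate = 200, syringe_volume = 500),
    arms = arms, out_dt = 0.1)
}

test_that("a deterministic cohort makes both arms and all subjects identical", {
  cfg <- tiny_config(n = 2, omega_scale = 0, prop = 0, add = 0)
  res <- run_trial(cfg)
  oc <- res$arms$open_loop$C4
  cc <- res$arms$closed_loop$C4
  expect_equal(oc[, 1], oc[, 2])
  expect_equal(oc[, 1], cc[, 1], tolerance = 1e-8)
  expect_equal(cc[, 1], cc[, 2])
  s <- summarize_ct_profiles(res$arms$open_loop, "C4")
  expect_true(all(s$hi95 - s$lo95 < 1e-9))
})

test_that("trials are reproducible from config and seed", {
  cfg <- tiny_config(n = 3)
  r1 <- run_trial(cfg)
  r2 <- run_trial(cfg)
  expect_identical(summarize_ct_profiles(r1$arms$closed_loop, "C4"),
                   summarize_ct_profiles(r2$arms$closed_loop, "C4"))
  expect_identical(as.data.frame(r1$cohort), as.data.frame(r2$cohort))
})

test_that("open-loop delivery is identical across subjects while closed-loop personalizes", {
  cfg <- tiny_config(n = 3)
  res <- run_trial(cfg)
  expect_length(res$arms$open_loop$profiles, 1)   # one shared schedule
  profs <- res$arms$closed_loop$profiles
  expect_false(identical(profs[[1]]$rates, profs[[2]]$rates))
})

test_that("cohort summaries use the empirical median and 95% interval", {
  grid <- c(0, 1)
  arm <- structure(list(arm = "x", grid = grid,
                        C4 = rbind(c(1, 2, 3), c(1, 2, 3)),
                        C1 = rbind(c(1, 2, 3), c(1, 2, 3))),
                   class = "arm_result")
  s <- summarize_ct_profiles(arm, "C4")
  expect_equal(s$median, c(2, 2))
  expect_true(all(s$lo95 <= s$median & s$median <= s$hi95))

  withr::with_seed(30, {
    vals <- matrix(rlnorm(4000, log(6), 0.3), nrow = 1)
    arm2 <- structure(list(arm = "x", grid = 0, C4 = vals, C1 = vals),
                      class = "arm_result")
    s2 <- summarize_ct_profiles(arm2, "C4")
    expect_equal(s2$median, 6, tolerance = 0.03)
    expect_equal(s2$hi95, 6 * exp(1.96 * 0.3), tolerance = 0.05)
    expect_equal(s2$lo95, 6 * exp(-1.96 * 0.3), tolerance = 0.05)
  })
})

test_that("band metrics reduce to the constructed geometry", {
  grid <- seq(0, 10, 0.5)
  n <- length(grid)
  # constant-width band: 8 +/- 1 around a 6 target is all outside 10%
  m <- rbind(rep(7, n), rep(9, n))
  arm <- structure(list(arm = "x", grid = grid, C4 = t(m), C1 = t(m)),
                   class = "arm_result")
  met <- accuracy_metrics(arm, target = 8, window = c(5, 10))
  expect_equal(met$band_area, 0.95 * 2 * 5, tolerance = 1e-6)
  expect_equal(met$within_10pct_fraction, 0)   # 7 and 9 both deviate 12.5%

  # zero-width band exactly on target
  m0 <- rbind(rep(6, n), rep(6, n))
  arm0 <- structure(list(arm = "x", grid = grid, C4 = t(m0), C1 = t(m0)),
                    class = "arm_result")
  met0 <- accuracy_metrics(arm0, target = 6, window = c(5, 10))
  expect_equal(met0$band_area, 0)
  expect_equal(met0$within_10pct_fraction, 1)
  expect_length(met0$flagged_subjects, 0)
  expect_error(accuracy_metrics(arm0, target = 0), "target")
})

test_that("the prediction-interval area grows with inter-individual variability", {
  areas <- vapply(c(0.25, 0.6, 1), function(sc) {
    cfg <- tiny_config(n = 40, omega_scale = sc, arms = "open_loop",
                       duration = 8, seed = 7)
    res <- run_trial(cfg)
    accuracy_metrics(res$arms$open_loop, 6, reference = res$reference)$band_area
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("closing the loop narrows the cohort prediction band (scaled scenario)", {
  cfg <- tiny_config(n = 25, duration = 10, seed = 17)
  res <- run_trial(cfg)
  ao <- accuracy_metrics(res$arms$open_loop, 6, reference = res$reference)
  ac <- accuracy_metrics(res$arms$closed_loop, 6, reference = res$reference)
  expect_lt(ac$band_area, ao$band_area)
})
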