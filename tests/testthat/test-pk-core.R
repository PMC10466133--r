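test_that("micro-constants follow the stated definitions and the mammillary convention", {
  rc <- derive_rate_constants(pk_params(CL = 1, V1 = 10, V2 = 20, V3 = 30,
                                        Q2 = 0.5, Q3 = 0.3, ke0 = 0.2))
  expect_identical(rc$k10, 0.1)          # CL/V1
  expect_identical(rc$k41, 0.2)          # ke0
  expect_identical(rc$k14, 2e-5)         # ke0/10000
  expect_identical(rc$k12, 0.05)         # Q2/V1
  expect_identical(rc$k21, 0.025)        # Q2/V2
  expect_identical(rc$k13, 0.03)         # Q3/V1
  expect_identical(rc$k31, 0.01)         # Q3/V3
})

test_that("invalid parameters are rejected with the offending field named", {
  expect_error(pk_params(-1, 10, 20, 30, 0.5, 0.3, 0.2), "CL")
  expect_error(pk_params(1, 0, 20, 30, 0.5, 0.3, 0.2), "V1")
  expect_error(pk_params(1, 10, 20, 30, 0.5, 0.3, Inf), "ke0")
})

test_that("the state equations have the printed structure", {
  rc <- derive_rate_constants(ref_params())
  # origin is an equilibrium with no input
  expect_identical(pk_rhs(c(0, 0, 0, 0), rc, U = 0), c(0, 0, 0, 0))
  # drug only in the central compartment feeds the peripherals at k12, k13
  d <- pk_rhs(c(10, 0, 0, 0), rc, U = 0)
  expect_equal(d[2], 10 * rc$k12)
  expect_equal(d[3], 10 * rc$k13)
  # the only mass loss is first-order elimination from the centre
  withr::with_seed(11, {
    for (i in 1:20) {
      st <- runif(4, 0, 50)
      U <- runif(1, 0, 100)
      d <- pk_rhs(st, rc, U)
      expect_equal(sum(d[1:3]), U - st[1] * rc$k10)
    }
  })
})

test_that("zero input from a drug-naive state stays identically zero", {
  traj <- simulate_pk(ref_params(), infusion_profile(0, 0, end = 10),
                      grid = seq(0, 10, 1))
  expect_true(all(traj[c("A1", "A2", "A3", "C1", "C4")] == 0))
})

test_that("numerical integration matches the analytic constant-rate solution", {
  withr::with_seed(42, {
    for (i in 1:20) {
      p <- random_params()
      U <- runif(1, 5, 150)
      tt <- c(0.5, 2, 10, 30)
      traj <- simulate_pk(p, infusion_profile(0, U, end = 31), grid = tt)
      an <- analytic_constant_infusion(p, U, tt)
      for (col in c("A1", "A2", "A3", "C4"))
        expect_lt(max(abs(traj[[col]] - an[[col]]) / pmax(an[[col]], 1e-12)), 1e-6)
    }
  })
})

test_that("infused drug is fully accounted for as retained plus eliminated", {
  withr::with_seed(7, {
    for (i in 1:5) {
      p <- random_params()
      prof <- infusion_profile(c(0, 1, 4, 7), c(runif(1, 50, 200), 0,
                                                runif(1, 5, 30), 10), end = 20)
      traj <- simulate_pk(p, prof, grid = seq(0, 20, 0.5))
      last <- nrow(traj)
      retained <- traj$A1[last] + traj$A2[last] + traj$A3[last]
      infused <- total_infused(prof, 20)
      expect_lt(abs(retained + traj$eliminated[last] - infused) / infused, 1e-6)
    }
  })
})

test_that("the system is linear: doubling the input doubles every response", {
  p <- ref_params()
  prof1 <- infusion_profile(c(0, 2), c(80, 15), end = 15)
  prof2 <- infusion_profile(c(0, 2), c(160, 30), end = 15)
  g <- seq(0, 15, 0.5)
  t1 <- simulate_pk(p, prof1, g)
  t2 <- simulate_pk(p, prof2, g)
  for (col in c("A1", "A2", "A3", "C1", "C4"))
    expect_equal(t2[[col]], 2 * t1[[col]], tolerance = 1e-7)
})

test_that("a constant infusion settles at C1 = U/CL with the effect site equilibrated", {
  p <- small_params()
  U <- 12
  # closed form at near-infinite time gives the steady state exactly
  ss <- analytic_constant_infusion(p, U, t = 1e5)
  expect_equal(ss$C1, U / p$CL, tolerance = 1e-9)
  expect_equal(ss$C4, ss$C1, tolerance = 1e-9)
  # the integrator approaches it on a finite (many-half-life) horizon
  traj <- simulate_pk(p, infusion_profile(0, U, end = 500), grid = c(100, 400))
  expect_equal(traj$C1[2], U / p$CL, tolerance = 1e-3)
})

test_that("trajectories stay non-negative for non-negative inputs", {
  withr::with_seed(13, {
    for (i in 1:5) {
      p <- random_params()
      prof <- infusion_profile(c(0, 0.5, 3), c(200, 0, runif(1, 0, 40)), end = 12)
      traj <- simulate_pk(p, prof, seq(0, 12, 0.25))
      expect_true(all(traj[c("A1", "A2", "A3", "C1", "C4")] >= -1e-9))
    }
  })
})

test_that("amounts convert to concentrations by the volume of distribution", {
  p <- pk_params(1, 10, 20, 40, 0.5, 0.3, 0.2)
  df <- data.frame(A1 = c(5, 0), A2 = c(10, 0), A3 = c(20, 0), C4 = c(1, 0))
  cc <- amounts_to_concentrations(df, p)
  expect_equal(cc$C1, c(0.5, 0))
  expect_equal(cc$C2, c(0.5, 0))
  expect_equal(cc$C3, c(0.5, 0))
  expect_equal(cc$C4, df$C4)          # already a concentration
  expect_equal(cc$C1 * p$V1, df$A1)   # round trip
})

test_that("simulation inputs are validated", {
  p <- ref_params()
  prof <- infusion_profile(0, 10, end = 5)
  expect_error(simulate_pk(p, prof, grid = c(0, 6)), "span")
  expect_error(simulate_pk(p, prof, grid = c(0, 3), init = c(-1, 0, 0, 0)),
               "non-negative")
})

test_that("trajectory and infusion-profile CSV export round-trips", {
  p <- ref_params()
  prof <- infusion_profile(c(0, 1.5), c(90, 12), end = 10)
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_infusion_csv(prof, f1)
  prof2 <- read_infusion_csv(f1)
  expect_equal(prof2$times, prof$times)
  expect_equal(prof2$rates, prof$rates)
  expect_equal(prof2$end, prof$end)

  traj <- simulate_pk(p, prof, seq(0, 10, 1))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, f2)
  back <- read.csv(f2)
  expect_named(back, c("time_min", "A1_mg", "A2_mg", "A3_mg",
                       "C1_mg_per_L", "C4_mg_per_L", "U_mg_per_min"))
  expect_equal(back$C1_mg_per_L, traj$C1)
})
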