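test_that("dose regimens are validated", {
  expect_error(dose_regimen(5, 6, interval_h = 4, n_doses = 3),
               "must not exceed")
  expect_error(dose_regimen(5, 0.25, interval_h = 4, n_doses = 12,
                            duration_h = 10), "too short")
  reg <- pediatric_regimen("neonate")
  expect_equal(reg$n_doses, 12)
  expect_equal(pediatric_regimen("child")$interval_h, 6)
})

test_that("zero dose yields an identically zero profile", {
  prof <- simulate_subject(test_model, list(age = 7),
                           dose_regimen(0, 0.25, interval_h = 4,
                                        n_doses = 3))
  expect_true(all(prof$conc == 0))
})

test_that("the ODE engine matches the one-compartment infusion solution", {
  # forced-linear limit, constant clearance: during a 2-h infusion
  #   C(t) = R0 / CL * (1 - exp(-k t)),  k = CL / V
  lin <- linearized_model()
  prof <- simulate_subject(lin, list(age = 30),
                           dose_regimen(5, 2, duration_h = 24),
                           points_per_interval = 200)
  cl <- attr(prof, "cl_linear")
  v <- attr(prof, "volume")
  k <- cl / v
  r0 <- attr(prof, "dose_mg") / 2
  t_inf <- 2
  analytic <- ifelse(prof$time <= t_inf,
                     r0 / cl * (1 - exp(-k * prof$time)),
                     r0 / cl * (1 - exp(-k * t_inf)) *
                       exp(-k * (prof$time - t_inf)))
  idx <- prof$time > 0.05
  expect_lt(max(abs(prof$conc[idx] / analytic[idx] - 1)), 0.005)
})

test_that("mass is conserved to 0.1% through multiple dosing", {
  prof <- simulate_subject(test_model, list(age = 14 / 365.25),
                           pediatric_regimen("neonate"))
  delivered <- attr(prof, "delivered_mg")
  residual <- delivered - attr(prof, "eliminated_mg") -
    attr(prof, "remaining_mg")
  expect_lt(abs(residual) / delivered, 0.001)
})

test_that("linear-regime exposure equals Dose / CL", {
  lin <- linearized_model()
  prof <- simulate_subject(lin, list(age = 30),
                           dose_regimen(5, 2, duration_h = 36))
  ex <- nca(prof)
  expect_equal(ex$auc_0_inf,
               attr(prof, "dose_mg") / attr(prof, "cl_linear"),
               tolerance = 0.01)
})

test_that("steady-state AUC over tau equals single-dose AUC to infinity", {
  # superposition in the linear regime
  lin <- linearized_model()
  subject <- list(age = 7)
  multi <- simulate_subject(lin, subject, pediatric_regimen("child"))
  ss <- nca(multi, tau = 6)
  single <- nca(simulate_subject(lin, subject,
                                 dose_regimen(12.5, 0.25, duration_h = 48)))
  expect_equal(ss$auc_tau, single$auc_0_inf, tolerance = 0.01)
})

test_that("saturable kinetics produce a supra-proportional dose response", {
  ex5 <- nca(simulate_subject(test_model, list(age = 30),
                              dose_regimen(5, 2, duration_h = 24)))
  ex20 <- nca(simulate_subject(test_model, list(age = 30),
                               dose_regimen(20, 2, duration_h = 24)))
  expect_gte(ex20$auc_0_inf, 4 * ex5$auc_0_inf)
})

test_that("population simulation is reproducible and its envelope is ordered", {
  reg <- dose_regimen(5, 2, duration_h = 12)
  a <- simulate_population(test_model, "adult", 5, reg, trials = 2, seed = 31)
  b <- simulate_population(test_model, "adult", 5, reg, trials = 2, seed = 31)
  expect_identical(a$conc, b$conc)
  expect_true(all(a$p05 <= a$mean + 1e-12))
  expect_true(all(a$mean <= a$p95 + 1e-12))

  # zero variability collapses the percentile band onto the mean
  z <- simulate_population(test_model, "child", 4, reg, trials = 1, seed = 2,
                           enzyme_cv = 0, vss_cv = 0, weight_cv = 0)
  # subjects still differ by sampled age; force a degenerate age window too
  same_age <- z$subjects$age
  expect_false(any(duplicated(same_age)))  # ages vary within the window
  d <- simulate_population(test_model, "adult", 4, reg, trials = 1, seed = 2,
                           enzyme_cv = 0, vss_cv = 0, weight_cv = 0)
  # adults share clamped physiology, so all profiles coincide
  expect_equal(max(d$p95 - d$p05), 0, tolerance = 1e-10)
})
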