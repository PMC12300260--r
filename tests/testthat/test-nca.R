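test_that("NCA reproduces closed-form one-compartment bolus metrics", {
  # CL = 20 L/h, V = 56 L, dose 350 mg: C0 = 6.25, AUCinf = 17.5
  cl <- 20; v <- 56; dose <- 350
  k <- cl / v
  tgrid <- seq(0, 24, by = 0.05)
  prof <- data.frame(time = tgrid, conc = dose / v * exp(-k * tgrid))
  ex <- nca(prof)
  expect_equal(ex$auc_0_inf, dose / cl, tolerance = 0.01)
  expect_equal(ex$lambda_z, k, tolerance = 0.01)
  expect_true(ex$lambda_z_reliable)
  expect_equal(ex$cmax, dose / v)
  expect_equal(ex$tmax, 0)
})

test_that("a flat zero profile yields zero metrics and no terminal slope", {
  prof <- data.frame(time = 0:10, conc = rep(0, 11))
  ex <- nca(prof)
  expect_equal(ex$cmax, 0)
  expect_equal(ex$auc_last, 0)
  expect_equal(ex$auc_0_inf, 0)
  expect_false(ex$lambda_z_reliable)
})

test_that("trapezoid error shrinks quadratically under grid refinement", {
  # non-exponential shape so neither branch of the rule is exact
  f <- function(t) t * exp(-t)
  auc_true <- 1 - 11 * exp(-10)   # integral over [0, 10]
  err <- vapply(c(0.2, 0.1, 0.05), function(h) {
    tg <- seq(0, 10, by = h)
    abs(nca(data.frame(time = tg, conc = f(tg)))$auc_last - auc_true)
  }, numeric(1))
  expect_lt(err[2], err[1] / 3)
  expect_lt(err[3], err[2] / 3)
})

test_that("fold errors behave as predicted/observed ratios", {
  expect_equal(fold_error(4.95, 4.74), 1.04, tolerance = 0.005)
  expect_equal(fold_error(53.6, 65.6), 0.82, tolerance = 0.005)
  expect_identical(fold_error(3.3, 3.3), 1)
  # reciprocal identity
  for (pair in list(c(2, 3), c(10, 4), c(0.3, 0.9))) {
    expect_equal(fold_error(pair[1], pair[2]) * fold_error(pair[2], pair[1]),
                 1)
  }
  expect_error(fold_error(1, 0))
})

test_that("verification joins predictions to observations with bounds flags", {
  obs <- observed_exposure()
  expect_equal(nrow(obs), 10)

  # the published predicted/observed pediatric pairs all verify
  published_pred <- data.frame(
    population = rep(c("child", "infant", "neonate"), each = 2),
    dose_mg_per_kg = 12.5,
    parameter = rep(c("cmax", "auc_tau"), 3),
    predicted = c(28.6, 35.7, 22.8, 39.1, 21.8, 53.6))
  rep1 <- verification_report(published_pred, obs)
  expect_true(all(rep1$within_bounds))
  expect_equal(rep1$fold_error[rep1$population == "neonate" &
                                 rep1$parameter == "auc_tau"],
               0.82, tolerance = 0.005)

  # a 3-fold overprediction fails the band
  bad <- data.frame(population = "adult", dose_mg_per_kg = 5,
                    parameter = "cmax", predicted = 3 * 4.74)
  expect_false(verification_report(bad, obs)$within_bounds)

  # empty observed table: empty report
  expect_equal(nrow(verification_report(bad, obs[0, ])), 0)

  # predictions lacking observations are kept with NA fold error
  extra <- data.frame(population = "adult", dose_mg_per_kg = 10,
                      parameter = "cmax", predicted = 9)
  rep2 <- verification_report(extra, obs)
  expect_true(is.na(rep2$fold_error))
  expect_false(rep2$within_bounds)
})
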