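test_that("noise-free data from each candidate form is recovered", {
  # three-phase piecewise: dense design so the breakpoints are identified
  d <- simulate_abundance_dataset(recovery_truth, 2001, noise_cv = 0,
                                  age_sampler = dense_age_grid)
  fit <- fit_ontogeny(d, "piecewise3")
  truth <- c(intercept1 = 100, slope1 = 90, breakpoint1 = 2,
             anchor2 = 300, slope2 = 10, breakpoint2 = 12)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$params[names(truth)] - truth) / truth), 0.01)
  # refit curve matches the generating curve
  expect_lt(max(abs(predict(fit, d$age_years) -
                      d$abundance_pmol_per_mg)), 1)

  # hill
  dh <- data.frame(age = seq(0.01, 30, length.out = 300))
  dh$abundance <- 50 + 400 * dh$age^2 / (2^2 + dh$age^2)
  fh <- fit_ontogeny(dh, "hill")
  th <- c(base = 50, emax = 400, age50 = 2, h = 2)
  expect_lt(max(abs(fh$params[names(th)] - th) / th), 0.01)

  # exponential
  de <- data.frame(age = seq(0, 30, length.out = 300))
  de$abundance <- 450 - 350 * exp(-0.5 * de$age)
  fe <- fit_ontogeny(de, "exponential")
  te <- c(A = 450, B = 350, k = 0.5)
  expect_lt(max(abs(fe$params[names(te)] - te) / te), 0.01)
})

test_that("degenerate designs are rejected", {
  same_age <- data.frame(age = rep(5, 30), abundance = runif(30, 50, 150))
  expect_error(fit_ontogeny(same_age, "piecewise3"), "single age")
  few <- data.frame(age = 1:4, abundance = c(10, 20, 30, 40))
  expect_error(fit_ontogeny(few, "piecewise3"), "at least")
  bad <- data.frame(age = c(1, 2), bogus = c(3, 4))
  expect_error(fit_ontogeny(bad, "piecewise3"), "columns")
})

test_that("model selection minimises AIC with a parsimony tie-break", {
  mk_fit <- function(form, aic, npar) {
    structure(list(form = form, params = numeric(0), rss = 1, aic = aic,
                   r2 = 0.5, n = 10, npar = npar, converged = TRUE),
              class = "ontogeny_fit")
  }
  # tie: fewer parameters wins
  tie <- list(mk_fit("hill", -100, 7), mk_fit("exponential", -100, 3))
  expect_identical(select_best(tie)$form, "exponential")
  # single fit: identity
  one <- list(mk_fit("logistic", 12, 4))
  expect_identical(select_best(one)$form, "logistic")
  # plain minimum
  expect_identical(
    select_best(list(mk_fit("hill", 5, 4), mk_fit("logistic", -2, 4)))$form,
    "logistic")
  expect_error(select_best(list()), "at least one")
})

test_that("AIC-based selection is invariant to abundance unit rescaling", {
  d <- simulate_abundance_dataset(recovery_truth, 150, noise_cv = 0.25,
                                  seed = 5)
  forms <- c("piecewise3", "piecewise_linear", "exponential")
  pick <- function(dat) {
    select_best(lapply(forms, function(f) fit_ontogeny(dat, f)))$form
  }
  d_scaled <- d
  d_scaled$abundance_pmol_per_mg <- d$abundance_pmol_per_mg * 1000
  expect_identical(pick(d), pick(d_scaled))
})

test_that("non-convergence of a nonlinear fit is flagged, not thrown", {
  # constant data offers no gradient for the logistic midpoint/steepness,
  # but whatever the optimizer does the result must be a valid fit object
  d <- data.frame(age = seq(0, 10, length.out = 30),
                  abundance = rep(100, 30) + rep(c(-1e-8, 1e-8), 15))
  fit <- fit_ontogeny(d, "logistic")
  expect_s3_class(fit, "ontogeny_fit")
  expect_true(is.logical(fit$converged))
  if (!fit$converged) expect_identical(fit$aic, Inf)
})

test_that("a fitted piecewise3 converts to an evaluable ontogeny model", {
  d <- simulate_abundance_dataset(recovery_truth, 800, noise_cv = 0,
                                  age_sampler = dense_age_grid)
  m <- as_ontogeny_model(fit_ontogeny(d, "piecewise3"), enzyme = "synthetic")
  expect_s3_class(m, "ontogeny_piecewise3")
  expect_equal(evaluate_abundance(m, 20), 400, tolerance = 1e-3)
})
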