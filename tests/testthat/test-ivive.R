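test_that("per-mg intrinsic clearance matches Vmax/Km in the linear range", {
  sys <- system_parameters(20)
  ont <- enzyme_ontogeny_table()
  kin <- load_compound()$kinetics
  s1a1 <- kin[kin$pathway == "SULT1A1", ]
  cl <- pathway_clint(s1a1, 20, 0, sys, ont, mw = 151.2)
  # unscale organ factors back to uL/min/mg: 1549/2400 = 0.645
  per_mg <- cl / (sys$cppgl * sys$liver_weight * 60e-6)
  expect_equal(per_mg, 1549 / 2400, tolerance = 1e-9)

  # saturation: CLint vanishes as the unbound concentration grows
  cl_hi <- pathway_clint(s1a1, 20, 1e9, sys, ont, mw = 151.2)
  expect_lt(cl_hi, cl * 1e-3)
  # and is monotone decreasing in concentration
  concs <- c(0, 10, 100, 1000)
  cls <- vapply(concs, function(cu)
    pathway_clint(s1a1, 20, cu, sys, ont, mw = 151.2), numeric(1))
  expect_true(all(diff(cls) < 0))

  # linearity: doubling Vmax doubles the linear-range CLint
  s2 <- s1a1
  s2$vmax <- s2$vmax * 2
  expect_equal(pathway_clint(s2, 20, 0, sys, ont, mw = 151.2), 2 * cl)
})

test_that("the well-stirred model obeys its limiting identities", {
  sys <- system_parameters(20)
  qh <- sys$hepatic_blood_flow
  fub <- sys$fu_plasma / sys$blood_plasma_ratio
  expect_identical(hepatic_clearance(0, sys), 0)
  expect_equal(hepatic_clearance(1e12, sys), qh, tolerance = 1e-6)
  # midpoint identity: fuB * CLint = Qh  =>  CLh = Qh / 2
  expect_equal(hepatic_clearance(qh / fub, sys), qh / 2)
  # concave and increasing, bounded by flow (uniform CLint spacing)
  cls <- vapply(seq(10, 1000, by = 90), hepatic_clearance,
                numeric(1), sys = sys)
  expect_true(all(diff(cls) > 0))
  expect_true(all(cls < qh))
  expect_true(all(diff(diff(cls)) < 0))
})

test_that("pathway fractions are a normalized decomposition at every age", {
  for (a in c(7 / 365.25, 0.5, 2, 7, 20, 60)) {
    bd <- fm_breakdown(test_model, a)
    expect_equal(sum(bd$fm), 1, tolerance = 1e-9)
    expect_true(all(bd$fm >= 0))
    expect_lt(attr(bd, "clh"),
              system_parameters(a)$hepatic_blood_flow)
    expect_setequal(bd$pathway, c(sultpbpk:::apap_pathways(), "renal"))
  }
})

test_that("fm is invariant to uniform rescaling of all Vmax values", {
  scaled <- test_model
  scaled$profile$kinetics$vmax <- scaled$profile$kinetics$vmax * 7
  bd0 <- fm_breakdown(test_model, 1)
  # renal fraction shifts when hepatic clearance changes, so compare the
  # hepatic pathways' shares of hepatic clearance
  hep0 <- bd0$fm[bd0$pathway != "renal"]
  bd1 <- fm_breakdown(scaled, 1)
  hep1 <- bd1$fm[bd1$pathway != "renal"]
  expect_equal(hep1 / sum(hep1), hep0 / sum(hep0), tolerance = 1e-9)
})

test_that("adult systemic clearance is anchored to the reference IV value", {
  bd <- fm_breakdown(test_model, 20)
  expect_equal(attr(bd, "total_clearance"), 19.7, tolerance = 1e-6)
  # even without calibration, raw IVIVE lands within the 0.5-2x band
  raw <- apap_model(calibrate = FALSE)
  total_raw <- attr(fm_breakdown(raw, 20), "total_clearance")
  expect_gt(total_raw, 19.7 * 0.5)
  expect_lt(total_raw, 19.7 * 2)
})
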