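test_that("built-in piecewise models reproduce the published segment values", {
  lib <- builtin_ontogeny_library()

  # segment intercepts and plateaus
  expect_equal(evaluate_abundance(lib$SULT1A1, 0), 107.8)
  expect_equal(evaluate_abundance(lib$SULT1A1, 50), 445.2)
  expect_equal(evaluate_abundance(lib$SULT1A3, 20), 97.2)
  expect_equal(evaluate_abundance(lib$SULT2A1, 20), 1095)
  expect_equal(evaluate_abundance(lib$SULT1B1, 20), 115)

  # mid-segment arithmetic
  expect_equal(evaluate_abundance(lib$SULT2A1, 1), 705.3 + 975.2 * 1)
  # SULT1A3 at exactly its first breakpoint falls on segment 2 ...
  expect_equal(evaluate_abundance(lib$SULT1A3, 2), 60)
  # ... and the segment-1 limit approaching it is 117.3 - 28.7*2 = 59.9
  expect_equal(evaluate_abundance(lib$SULT1A3, 2 - 1e-9), 59.9,
               tolerance = 1e-6)

  # evaluation is exactly constant beyond the final breakpoint
  ages <- seq(12.6 + 1e-9, 100, length.out = 50)
  expect_true(all(evaluate_abundance(lib$SULT1A1, ages) == 445.2))
})

test_that("built-in models are positive at every age and reject negative ages", {
  lib <- builtin_ontogeny_library()
  grid <- seq(0, 100, by = 0.25)
  for (m in lib) {
    expect_true(all(evaluate_abundance(m, grid) > 0))
  }
  expect_error(evaluate_abundance(lib$SULT1A1, -0.1), "non-negative")
  expect_error(relative_activity(lib$SULT1A3, -1), "non-negative")
})

test_that("relative activity is the ratio to the adult reference", {
  lib <- builtin_ontogeny_library()
  expect_equal(relative_activity(lib$SULT1A1, 0), 107.8 / 445.2)
  expect_equal(relative_activity(lib$SULT1A3, 0), 117.3 / 97.2)
  # identity at the reference age, any reference
  for (ref in c(15, 20, 30)) {
    expect_identical(relative_activity(lib$SULT2A1, ref, ref), 1)
  }
  # constant profile: unity everywhere
  expect_equal(relative_activity(lib$SULT1E1, c(0, 1, 40)), rep(1, 3))
  expect_equal(evaluate_abundance(lib$SULT1E1, c(0, 80)), c(1, 1))
})

test_that("the library carries all five SULT isozymes", {
  lib <- builtin_ontogeny_library()
  expect_setequal(names(lib),
                  c("SULT1A1", "SULT1A3", "SULT2A1", "SULT1B1", "SULT1E1"))
  # SULT1B1 is present even though acetaminophen has no SULT1B1 pathway
  expect_s3_class(lib$SULT1B1, "ontogeny_piecewise3")
})

test_that("constructor rejects invalid parameterizations", {
  expect_error(ontogeny_piecewise3(1, 1, 5, 1, 1, 2, 10), "breakpoint")
  expect_error(ontogeny_piecewise3(1, 1, 1, 1, 1, 2, -3), "plateau")
  expect_error(ontogeny_constant(0), "positive")
})
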