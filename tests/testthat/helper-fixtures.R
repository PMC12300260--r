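# Shared fixtures: built once per test run.

test_model <- apap_model()

# Model variant with saturation effectively removed (Km and Vmax scaled by
# the same large factor leaves every linear-range CLint unchanged while
# pushing Michaelis constants far above any simulated concentration).
linearized_model <- function(model = test_model, factor = 1e6) {
  kin <- model$profile$kinetics
  kin$km <- kin$km * factor
  kin$vmax <- kin$vmax * factor
  model$profile$kinetics <- kin
  model
}

# Dense deterministic age grid for noise-free regression oracles.
dense_age_grid <- function(n) seq(0, 25, length.out = n)

# A continuous three-phase truth used in recovery tests (plateau equals
# the segment-2 value at breakpoint2, as the fitter parameterises it).
recovery_truth <- ontogeny_piecewise3(100, 90, 2, 300, 10, 12,
                                      plateau = 300 + 10 * 10,
                                      enzyme = "synthetic")

fm_total <- function(breakdown, family) {
  if (family %in% breakdown$pathway) {
    breakdown$fm[breakdown$pathway == family]
  } else {
    sum(breakdown$fm[startsWith(breakdown$pathway, family)])
  }
}
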