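# Population verification experiments: adult single-dose infusions and
# pediatric multiple-dose trials, summarised in the convention of the
# clinical reports they are compared with (mean +/- SD for adults, median
# and range for pediatric groups).

#' Adult verification experiment
#'
#' Simulates a healthy-volunteer population (default 100 subjects, ages
#' 20-50) receiving single 2-h IV infusions of 5 and 20 mg/kg, runs
#' non-compartmental analysis per subject and summarises Cmax and
#' AUC(0-inf) as mean +/- SD.
#'
#' @param model an [apap_model()].
#' @param n number of virtual subjects per dose level.
#' @param seed integer seed.
#' @param doses dose levels in mg/kg.
#' @return Data frame with columns `population`, `dose_mg_per_kg`,
#'   `parameter`, `predicted` (mean), `pred_sd`, `n`.
#' @export
adult_verification <- function(model, n = 100, seed = NULL,
                               doses = c(5, 20)) {
  rows <- list()
  for (d in seq_along(doses)) {
    regimen <- dose_regimen(doses[d], 2, duration_h = 24)
    pop <- simulate_population(model, "adult", n_per_trial = n,
                               regimen = regimen, trials = 1,
                               seed = child_seed(seed, d))
    metrics <- lapply(pop$profiles, nca)
    cmax <- vapply(metrics, `[[`, numeric(1), "cmax")
    auc <- vapply(metrics, `[[`, numeric(1), "auc_0_inf")
    rows[[d]] <- data.frame(
      population = "adult", dose_mg_per_kg = doses[d],
      parameter = c("cmax", "auc_inf"),
      predicted = c(mean(cmax), mean(auc)),
      pred_sd = c(stats::sd(cmax), stats::sd(auc)),
      n = n)
  }
  do.call(rbind, rows)
}

#' Pediatric verification experiment
#'
#' Simulates the multiple-dose IV trial design in neonates, infants and
#' children (12.5 mg/kg over 15 min, 48 h of therapy; 10 trials of 2, 13
#' and 9 subjects respectively by default) and summarises steady-state
#' Cmax and AUC over the final complete dosing interval as
#' median (range) across all subjects.
#'
#' @param model an [apap_model()].
#' @param seed integer seed.
#' @param trials trials per group.
#' @param design named list of subjects per trial for each group.
#' @param intervals named list of dosing intervals (h) per group;
#'   defaults to the group defaults of [pediatric_regimen()].
#' @return Data frame with columns `population`, `dose_mg_per_kg`,
#'   `interval_h`, `parameter`, `predicted` (median), `pred_low`,
#'   `pred_high`, `n`.
#' @export
pediatric_verification <- function(model, seed = NULL, trials = 10,
                                   design = list(neonate = 2, infant = 13,
                                                 child = 9),
                                   intervals = NULL) {
  rows <- list()
  for (g in names(design)) {
    interval <- (intervals[[g]] %||% NULL) %||% age_group_row(g)$interval_h
    regimen <- pediatric_regimen(g, interval_h = interval)
    pop <- simulate_population(model, g, n_per_trial = design[[g]],
                               regimen = regimen, trials = trials,
                               seed = child_seed(seed, match(g, names(design))))
    metrics <- lapply(pop$profiles, nca, tau = interval)
    cmax <- vapply(metrics, `[[`, numeric(1), "cmax_tau")
    auc <- vapply(metrics, `[[`, numeric(1), "auc_tau")
    rows[[g]] <- data.frame(
      population = g, dose_mg_per_kg = regimen$dose_per_kg,
      interval_h = interval,
      parameter = c("cmax", "auc_tau"),
      predicted = c(median(cmax), median(auc)),
      pred_low = c(min(cmax), min(auc)),
      pred_high = c(max(cmax), max(auc)),
      n = nrow(pop$conc))
  }
  do.call(rbind, rows)
}
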