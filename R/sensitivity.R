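# Km/Vmax perturbation sweeps: deterministic representative-subject
# simulations quantifying how competitive inhibition (Km up),
# mechanism-based inhibition (Vmax down) and induction (Vmax up) of a
# SULT pathway would shift acetaminophen steady-state exposure per age
# group, reported as AUC and Cmax ratios to baseline.

#' Default log-spaced perturbation factors
#'
#' Km sweeps cover a 10-fold increase from baseline in 10 log-distributed
#' steps; Vmax sweeps cover a +/-10-fold range in 20 log-distributed steps
#' plus the exact baseline factor 1.
#'
#' @param parameter `"km"` or `"vmax"`.
#' @return Sorted numeric vector of multipliers including 1.
#' @export
sweep_factors <- function(parameter = c("km", "vmax")) {
  parameter <- match.arg(parameter)
  f <- switch(parameter,
              km = 10^seq(0, 1, length.out = 10),
              vmax = sort(unique(c(1, 10^seq(-1, 1, length.out = 20)))))
  f[abs(f - 1) < 1e-12] <- 1
  f
}

# Multiply one pathway's Km or Vmax by `factor`, keeping the baseline
# IVIVE calibration fixed (the perturbation represents an interaction,
# not a re-derivation of the model).
perturb_kinetics <- function(model, pathway, parameter, factor) {
  stopifnot(inherits(model, "pbpk_model"), factor > 0)
  kin <- model$profile$kinetics
  i <- match(pathway, kin$pathway)
  if (is.na(i)) stop("pathway not in compound profile: ", pathway)
  kin[[parameter]][i] <- kin[[parameter]][i] * factor
  model$profile$kinetics <- kin
  model
}

#' Run a Km or Vmax sensitivity sweep
#'
#' For each age group a deterministic representative subject (mid-window
#' age, growth-model weight, all variability multipliers 1) is simulated
#' under the group's default regimen at every perturbation factor;
#' steady-state AUC and Cmax over the final complete dosing interval are
#' expressed as ratios to the unperturbed baseline.
#'
#' @param model an [apap_model()].
#' @param pathway perturbed pathway (e.g. `"SULT1A1"`).
#' @param parameter `"km"` or `"vmax"`.
#' @param groups age groups to evaluate.
#' @param factors perturbation multipliers; defaults to
#'   [sweep_factors()] for the parameter.  Factor 1 is always evaluated.
#' @return Data frame of class `sweep_result` with columns `group`,
#'   `pathway`, `parameter`, `factor`, `scenario`, `auc_ratio`,
#'   `cmax_ratio`.
#' @export
#' @examples
#' \donttest{
#' model <- apap_model()
#' run_sweep(model, "SULT1A1", "km", groups = "neonate",
#'           factors = c(1, 10))
#' }
run_sweep <- function(model, pathway, parameter = c("km", "vmax"),
                      groups = c("neonate", "infant", "child"),
                      factors = NULL) {
  parameter <- match.arg(parameter)
  factors <- sort(unique(c(1, factors %||% sweep_factors(parameter))))
  rows <- list()
  for (g in groups) {
    row <- age_group_row(g)
    regimen <- pediatric_regimen(g)
    subject <- list(age = row$rep_age)
    tau <- regimen$interval_h
    base <- nca(simulate_subject(model, subject, regimen), tau = tau)
    for (f in factors) {
      m <- if (f == 1) model else
        perturb_kinetics(model, pathway, parameter, f)
      ex <- if (f == 1) base else
        nca(simulate_subject(m, subject, regimen), tau = tau)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, pathway = pathway, parameter = parameter, factor = f,
        scenario = classify_direction(parameter, f),
        auc_ratio = ex$auc_tau / base$auc_tau,
        cmax_ratio = ex$cmax_tau / base$cmax_tau)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Label the interaction scenario a perturbation emulates
#'
#' Increasing Km imitates competitive inhibition; decreasing Vmax imitates
#' mechanism-based inhibition; increasing Vmax imitates induction.
#'
#' @param parameter `"km"` or `"vmax"`.
#' @param factor perturbation multiplier(s).
#' @return Character vector of scenario labels (`"baseline"` at factor 1).
#' @export
classify_direction <- function(parameter = c("km", "vmax"), factor) {
  parameter <- match.arg(parameter)
  stopifnot(all(factor > 0))
  ifelse(factor == 1, "baseline",
         if (parameter == "km") {
           ifelse(factor > 1, "competitive_inhibition", "affinity_increase")
         } else {
           ifelse(factor > 1, "induction", "mechanism_based_inhibition")
         })
}
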