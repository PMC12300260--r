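# Non-compartmental analysis and fold-error verification of exposure
# predictions against observed clinical values.

# Linear-up/log-down trapezoid over one step.
trap_step <- function(t1, t2, c1, c2) {
  dt <- t2 - t1
  if (c2 < c1 && c2 > 0) {
    (c1 - c2) / log(c1 / c2) * dt
  } else {
    (c1 + c2) / 2 * dt
  }
}

auc_trapezoid <- function(time, conc) {
  if (length(time) < 2) return(0)
  sum(vapply(seq_len(length(time) - 1), function(i)
    trap_step(time[i], time[i + 1], conc[i], conc[i + 1]), numeric(1)))
}

# Terminal slope: log-linear regression on the longest strictly-declining
# positive tail (>= 3 points).  Returns list(lambda_z, n_points, reliable).
terminal_slope <- function(time, conc) {
  n <- length(conc)
  k <- 1
  while (k < n && conc[n - k] > conc[n - k + 1] && conc[n - k] > 0) {
    k <- k + 1
  }
  idx <- (n - k + 1):n
  idx <- idx[conc[idx] > 0]
  if (length(idx) < 3) {
    return(list(lambda_z = NA_real_, n_points = length(idx),
                reliable = FALSE))
  }
  fit <- lm.fit(cbind(1, time[idx]), log(conc[idx]))
  lam <- -coef(fit)[[2]]
  list(lambda_z = lam, n_points = length(idx),
       reliable = is.finite(lam) && lam > 0)
}

#' Non-compartmental exposure analysis
#'
#' Computes the standard exposure metrics from a concentration-time
#' profile: Cmax/Tmax, AUC to the last observation (linear-up/log-down
#' trapezoid), the terminal rate constant lambda_z (log-linear regression
#' on the last >= 3 strictly declining positive points),
#' `AUC_0-inf = AUC_last + C_last / lambda_z`, and -- when `tau` is given
#' -- the steady-state metrics over the final dosing interval
#' `[t_end - tau, t_end]` (`auc_tau`, `cmax_tau`).
#'
#' @param profile a [simulate_subject()] result, or any data frame with
#'   columns `time` (h) and `conc` (mg/L).
#' @param tau dosing interval (h) over which to report steady-state
#'   metrics; `NULL` for single-dose metrics only.
#' @return List of class `exposure_summary`: `cmax`, `tmax`, `auc_last`,
#'   `auc_0_inf`, `lambda_z`, `lambda_z_reliable`, and with `tau` also
#'   `auc_tau` and `cmax_tau`.
#' @export
#' @examples
#' prof <- simulate_subject(apap_model(), list(age = 30), dose_regimen(5, 2))
#' nca(prof)$auc_0_inf
nca <- function(profile, tau = NULL) {
  time <- profile$time
  conc <- profile$conc
  stopifnot(length(time) >= 2, all(diff(time) > 0), all(conc >= 0))
  cmax <- max(conc)
  out <- list(cmax = cmax, tmax = time[which.max(conc)],
              auc_last = auc_trapezoid(time, conc))
  if (cmax == 0) {
    out <- c(out, list(auc_0_inf = 0, lambda_z = NA_real_,
                       lambda_z_reliable = FALSE))
  } else {
    ts <- terminal_slope(time, conc)
    out$lambda_z <- ts$lambda_z
    out$lambda_z_reliable <- ts$reliable
    out$auc_0_inf <- if (ts$reliable) {
      out$auc_last + conc[length(conc)] / ts$lambda_z
    } else {
      NA_real_
    }
  }
  if (!is.null(tau)) {
    t_end <- time[length(time)]
    sel <- time >= t_end - tau - 1e-9
    out$auc_tau <- auc_trapezoid(time[sel], conc[sel])
    out$cmax_tau <- if (any(sel)) max(conc[sel]) else NA_real_
  }
  structure(out, class = "exposure_summary")
}

#' Fold error of a prediction
#'
#' `predicted / observed`; the conventional PBPK acceptance band is
#' 0.5-2.0.
#'
#' @param predicted,observed positive exposure values.
#' @export
#' @examples
#' fold_error(4.95, 4.74)
fold_error <- function(predicted, observed) {
  stopifnot(all(observed > 0))
  predicted / observed
}

#' Observed clinical exposure values
#'
#' Literature values for IV acetaminophen used in model verification:
#' adult healthy volunteers after 2-h infusions of 5 and 20 mg/kg
#' (Clements et al. 1984; mean, SD where reported) and pediatric
#' steady-state exposure under repeated 15-min infusions of 12.5 mg/kg
#' (Zuppa et al. 2011; median with range).
#'
#' @return Data frame with columns `population`, `dose_mg_per_kg`,
#'   `interval_h`, `parameter` (`cmax`, `auc_inf` or `auc_tau`),
#'   `observed`, `obs_sd`, `obs_low`, `obs_high`.
#' @export
observed_exposure <- function() {
  path <- system.file("extdata", "observed-exposure.csv",
                      package = "sultpbpk")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Verification report: predictions vs observations with fold errors
#'
#' Joins predicted and observed exposure values on population, dose and
#' parameter, computes fold errors and flags each row against the 0.5-2.0
#' acceptance band.
#'
#' @param predicted data frame with columns `population`, `dose_mg_per_kg`,
#'   `parameter`, `predicted` (and optionally extra columns such as
#'   `pred_low`/`pred_high`).
#' @param observed data frame as returned by [observed_exposure()]; rows
#'   without a matching prediction are dropped.  With an empty observed
#'   table an empty report is returned; predictions without observations
#'   are kept with `NA` fold errors.
#' @return The joined data frame with `fold_error` and `within_bounds`
#'   columns.
#' @export
verification_report <- function(predicted, observed = observed_exposure()) {
  keys <- c("population", "dose_mg_per_kg", "parameter")
  stopifnot(all(keys %in% names(predicted)))
  if (nrow(observed) == 0) {
    return(predicted[0, c(keys, "predicted"), drop = FALSE])
  }
  out <- merge(predicted,
               observed[, c(keys, "observed", "obs_low", "obs_high")],
               by = keys, all.x = TRUE, sort = FALSE)
  out$fold_error <- ifelse(is.na(out$observed), NA_real_,
                           fold_error(out$predicted,
                                      pmax(out$observed, .Machine$double.eps)))
  out$within_bounds <- !is.na(out$fold_error) &
    out$fold_error >= 0.5 & out$fold_error <= 2.0
  out
}
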