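# Regression machinery for enzyme ontogeny: candidate functional forms,
# unweighted least squares (multi-start where nonlinear), and AIC-based
# model selection.
#
# Candidate parameterisations (conventional ontogeny forms):
#   exponential      : A - B * exp(-k * age)
#   hill             : base + emax * age^h / (age50^h + age^h)
#   logistic         : base + L / (1 + exp(-k * (age - x0)))
#   piecewise_linear : two connected linear segments with one free breakpoint
#   piecewise3       : three-phase piecewise linear (first segment free,
#                      second segment anchored at breakpoint1, constant
#                      plateau beyond breakpoint2 tied to segment-2
#                      continuity); breakpoints are free parameters
#
# Breakpoints are estimated by a grid over age quantiles followed by
# Nelder-Mead refinement of the profiled residual sum of squares (the
# linear coefficients are solved exactly for any breakpoint candidate).

#' Candidate ontogeny model forms
#'
#' @return Character vector of the supported functional forms.
#' @export
ontogeny_forms <- function() {
  c("exponential", "hill", "logistic", "piecewise_linear", "piecewise3")
}

form_npar <- function(form) {
  switch(form,
         exponential = 3L, hill = 4L, logistic = 4L,
         piecewise_linear = 4L, piecewise3 = 6L,
         stop("unknown form: ", form))
}

form_predict <- function(form, params, age) {
  p <- as.list(params)
  switch(form,
    exponential = p$A - p$B * exp(-p$k * age),
    hill = p$base + p$emax * age^p$h / (p$age50^p$h + age^p$h),
    logistic = p$base + p$L / (1 + exp(-p$k * (age - p$x0))),
    piecewise_linear =
      p$intercept + p$slope1 * pmin(age, p$breakpoint) +
        p$slope2 * pmax(age - p$breakpoint, 0),
    piecewise3 = {
      ifelse(age < p$breakpoint1,
             p$intercept1 + p$slope1 * age,
             p$anchor2 + p$slope2 * (pmin(age, p$breakpoint2) - p$breakpoint1))
    },
    stop("unknown form: ", form))
}

# ---- linear sub-solvers for the piecewise forms -----------------------------

# Solve the linear coefficients of the 3-phase model for fixed breakpoints.
# Returns list(params, rss) or NULL when the design is unidentifiable.
pw3_solve <- function(age, y, bp1, bp2) {
  seg1 <- age < bp1
  if (sum(seg1) < 2 || sum(!seg1) < 2) return(NULL)
  if (length(unique(age[seg1])) < 2) return(NULL)
  x2 <- pmin(age, bp2) - bp1
  X <- cbind(i1 = as.numeric(seg1), s1 = ifelse(seg1, age, 0),
             a2 = as.numeric(!seg1), s2 = ifelse(seg1, 0, x2))
  fit <- lm.fit(X, y)
  if (fit$rank < 4L) return(NULL)
  b <- coef(fit)
  params <- c(intercept1 = unname(b["i1"]), slope1 = unname(b["s1"]),
              breakpoint1 = bp1, anchor2 = unname(b["a2"]),
              slope2 = unname(b["s2"]), breakpoint2 = bp2)
  list(params = params, rss = sum(fit$residuals^2))
}

pwl_solve <- function(age, y, bp) {
  lo <- age < bp
  if (sum(lo) < 2 || sum(!lo) < 2) return(NULL)
  X <- cbind(1, pmin(age, bp), pmax(age - bp, 0))
  fit <- lm.fit(X, y)
  if (fit$rank < 3L) return(NULL)
  b <- coef(fit)
  params <- c(intercept = b[[1]], slope1 = b[[2]], breakpoint = bp,
              slope2 = b[[3]])
  list(params = params, rss = sum(fit$residuals^2))
}

fit_piecewise3 <- function(age, y) {
  qs <- unique(as.numeric(quantile(age, seq(0.05, 0.95, by = 0.05))))
  grid <- expand.grid(bp1 = qs, bp2 = qs)
  grid <- grid[grid$bp2 > grid$bp1 & grid$bp1 > 0, , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    sol <- pw3_solve(age, y, grid$bp1[i], grid$bp2[i])
    if (!is.null(sol) && (is.null(best) || sol$rss < best$rss)) best <- sol
  }
  if (is.null(best)) {
    stop("piecewise3 fit is unidentifiable: ages must span both sides of ",
         "each candidate breakpoint with at least two points per phase")
  }
  # local refinement of the profiled RSS over (bp1, bp2)
  obj <- function(b) {
    if (b[1] <= min(age) || b[2] >= max(age) || b[2] <= b[1]) return(Inf)
    sol <- pw3_solve(age, y, b[1], b[2])
    if (is.null(sol)) Inf else sol$rss
  }
  opt <- optim(c(best$params[["breakpoint1"]], best$params[["breakpoint2"]]),
               obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 500))
  if (is.finite(opt$value) && opt$value < best$rss) {
    best <- pw3_solve(age, y, opt$par[1], opt$par[2])
  }
  list(params = best$params, rss = best$rss, converged = TRUE)
}

fit_piecewise_linear <- function(age, y) {
  qs <- unique(as.numeric(quantile(age, seq(0.05, 0.95, by = 0.025))))
  best <- NULL
  for (bp in qs[qs > 0]) {
    sol <- pwl_solve(age, y, bp)
    if (!is.null(sol) && (is.null(best) || sol$rss < best$rss)) best <- sol
  }
  if (is.null(best)) stop("piecewise_linear fit is unidentifiable")
  obj <- function(b) {
    if (b <= min(age) || b >= max(age)) return(Inf)
    sol <- pwl_solve(age, y, b)
    if (is.null(sol)) Inf else sol$rss
  }
  opt <- optim(best$params[["breakpoint"]], obj, method = "Brent",
               lower = min(age) + 1e-9, upper = max(age) - 1e-9)
  if (is.finite(opt$value) && opt$value < best$rss) {
    best <- pwl_solve(age, y, opt$par)
  }
  list(params = best$params, rss = best$rss, converged = TRUE)
}

# ---- nonlinear forms via multi-start Levenberg-Marquardt --------------------

nls_starts <- function(form, age, y) {
  rng <- max(y) - min(y)
  amax <- max(age)
  q <- as.numeric(quantile(age, c(0.25, 0.5, 0.75)))
  switch(form,
    exponential = {
      ks <- c(0.2, 1, 5) / max(amax, 1)
      do.call(rbind, lapply(ks, function(k)
        c(A = max(y), B = rng * sign(y[which.max(age)] - y[which.min(age)]),
          k = k)))
    },
    hill = do.call(rbind, lapply(q, function(a50) rbind(
      c(base = min(y), emax = rng, age50 = a50, h = 1),
      c(base = min(y), emax = rng, age50 = a50, h = 2)))),
    logistic = do.call(rbind, lapply(q, function(x0) rbind(
      c(base = min(y), L = rng, k = 1, x0 = x0),
      c(base = min(y), L = rng, k = 5 / max(amax, 1), x0 = x0)))),
    stop("no nonlinear starts for form: ", form))
}

fit_nonlinear <- function(form, age, y) {
  fml <- switch(form,
    exponential = y ~ A - B * exp(-k * age),
    hill = y ~ base + emax * age^h / (age50^h + age^h),
    logistic = y ~ base + L / (1 + exp(-k * (age - x0))))
  lower <- switch(form,
    exponential = c(A = -Inf, B = -Inf, k = 1e-6),
    hill = c(base = -Inf, emax = -Inf, age50 = 1e-4, h = 0.1),
    logistic = c(base = -Inf, L = -Inf, k = 1e-6, x0 = -Inf))
  starts <- nls_starts(form, age, y)
  dat <- data.frame(age = age, y = y)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, data = dat, start = as.list(starts[i, ]),
                        lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(params = coef(fit), rss = rss, converged = TRUE)
    }
  }
  if (is.null(best)) {
    best <- list(params = setNames(rep(NA_real_, ncol(starts)),
                                   colnames(starts)),
                 rss = NA_real_, converged = FALSE)
  }
  best
}

# ---- public fitting interface ----------------------------------------------

normalize_abundance_records <- function(records) {
  nm <- names(records)
  age_col <- intersect(c("age", "age_years"), nm)[1]
  ab_col <- intersect(c("abundance", "abundance_pmol_per_mg"), nm)[1]
  if (is.na(age_col) || is.na(ab_col)) {
    stop("`records` must have columns age/age_years and ",
         "abundance/abundance_pmol_per_mg")
  }
  out <- data.frame(age = as.numeric(records[[age_col]]),
                    abundance = as.numeric(records[[ab_col]]))
  if (any(!is.finite(out$age)) || any(out$age < 0)) {
    stop("ages must be finite and non-negative")
  }
  if (any(!is.finite(out$abundance)) || any(out$abundance <= 0)) {
    stop("abundances must be finite and positive")
  }
  out
}

#' Fit an ontogeny model to abundance-versus-age records
#'
#' Unweighted, unstratified least squares of a candidate functional form to
#' individual abundance observations.  Linear-in-parameters forms are
#' solved exactly for any breakpoint candidate; breakpoints themselves are
#' located by a grid over age quantiles plus local refinement.  Nonlinear
#' forms use multi-start Levenberg-Marquardt.  Non-convergence after all
#' starts is reported through `converged = FALSE` (with `aic = Inf`), not
#' as an error.
#'
#' @param records data frame with columns `age`/`age_years` and
#'   `abundance`/`abundance_pmol_per_mg`.
#' @param form one of [ontogeny_forms()].
#' @return An object of class `ontogeny_fit`: list with elements `form`,
#'   `params` (named numeric), `rss`, `aic`, `r2`, `n`, `npar`,
#'   `converged`.  `aic = n * log(rss / n) + 2 * (npar + 1)`, the standard
#'   least-squares form counting the residual variance as a parameter.
#' @seealso [select_best()], [predict.ontogeny_fit()], [as_ontogeny_model()]
#' @export
fit_ontogeny <- function(records, form = ontogeny_forms()) {
  form <- match.arg(form)
  dat <- normalize_abundance_records(records)
  n <- nrow(dat)
  k <- form_npar(form)
  if (n < k + 2L) {
    stop(sprintf("need at least %d records to fit a %d-parameter %s model",
                 k + 2L, k, form))
  }
  if (length(unique(dat$age)) < 2L) {
    stop("records at a single age are unidentifiable for any ontogeny form")
  }
  res <- switch(form,
    piecewise3 = fit_piecewise3(dat$age, dat$abundance),
    piecewise_linear = fit_piecewise_linear(dat$age, dat$abundance),
    fit_nonlinear(form, dat$age, dat$abundance))
  tss <- sum((dat$abundance - mean(dat$abundance))^2)
  rss <- res$rss
  aic <- if (isTRUE(res$converged) && is.finite(rss) && rss > 0) {
    n * log(rss / n) + 2 * (k + 1)
  } else if (isTRUE(res$converged) && isTRUE(rss == 0)) {
    -Inf  # perfect fit
  } else {
    Inf
  }
  structure(list(form = form, params = res$params, rss = rss, aic = aic,
                 r2 = if (is.finite(rss) && tss > 0) 1 - rss / tss else NA_real_,
                 n = n, npar = k, converged = isTRUE(res$converged)),
            class = "ontogeny_fit")
}

#' @export
print.ontogeny_fit <- function(x, ...) {
  cat(sprintf("<ontogeny_fit> form = %s (n = %d, npar = %d)\n",
              x$form, x$n, x$npar))
  cat(sprintf("  rss = %.4g, aic = %.4g, r2 = %.4g, converged = %s\n",
              x$rss, x$aic, x$r2, x$converged))
  print(round(x$params, 4))
  invisible(x)
}

#' Predict abundance from a fitted ontogeny model
#'
#' @param object an [fit_ontogeny()] result.
#' @param age ages (years) at which to evaluate the fitted curve.
#' @param ... unused.
#' @export
predict.ontogeny_fit <- function(object, age, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  form_predict(object$form, object$params, age)
}

#' Convert a fitted three-phase piecewise model to an `ontogeny_model`
#'
#' The plateau is the segment-2 value at `breakpoint2` (the fitted model is
#' continuous there by construction).
#'
#' @param fit an `ontogeny_fit` with `form = "piecewise3"`.
#' @param enzyme optional enzyme label for the resulting model.
#' @export
as_ontogeny_model <- function(fit, enzyme = NULL) {
  stopifnot(inherits(fit, "ontogeny_fit"), fit$form == "piecewise3",
            fit$converged)
  p <- as.list(fit$params)
  ontogeny_piecewise3(p$intercept1, p$slope1, p$breakpoint1, p$anchor2,
                      p$slope2, p$breakpoint2,
                      plateau = p$anchor2 +
                        p$slope2 * (p$breakpoint2 - p$breakpoint1),
                      enzyme = enzyme)
}

#' Select the best ontogeny fit by AIC
#'
#' Returns the fit with the minimum AIC; exact ties are broken in favour of
#' the form with fewer parameters.
#'
#' @param fits list of `ontogeny_fit` objects (fitted to the same records).
#' @return The winning `ontogeny_fit`.
#' @export
select_best <- function(fits) {
  if (length(fits) == 0) stop("`fits` must contain at least one fit")
  stopifnot(all(vapply(fits, inherits, logical(1), "ontogeny_fit")))
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  npars <- vapply(fits, `[[`, numeric(1), "npar")
  fits[[order(aics, npars)[1]]]
}
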