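#' Three-phase piecewise ontogeny model
#'
#' Constructs a three-phase piecewise-linear model of enzyme abundance
#' versus postnatal age: a first linear segment below `breakpoint1`, a
#' second linear segment anchored at `breakpoint1` and running to
#' `breakpoint2`, and a constant adult plateau beyond `breakpoint2`.
#' Segments are evaluated exactly as parameterised; the model is allowed to
#' be discontinuous at the breakpoints (no smoothing is applied), which
#' preserves fidelity to published fitted equations whose printed segment
#' limits do not always agree.
#'
#' @param intercept1,slope1 intercept (pmol/mg cytosolic protein) and slope
#'   (pmol/mg/year) of the first segment, `abundance = intercept1 +
#'   slope1 * age` for `age < breakpoint1`.
#' @param breakpoint1,breakpoint2 phase boundaries in years,
#'   `0 < breakpoint1 < breakpoint2`.
#' @param anchor2,slope2 second segment `abundance = anchor2 + slope2 *
#'   (age - breakpoint1)` for `breakpoint1 <= age <= breakpoint2`.
#' @param plateau constant abundance (pmol/mg) for `age > breakpoint2`.
#' @param enzyme optional enzyme label (e.g. `"SULT1A1"`).
#' @return An object of class `c("ontogeny_piecewise3", "ontogeny_model")`.
#' @seealso [ontogeny_constant()], [evaluate_abundance()],
#'   [builtin_ontogeny_library()]
#' @export
#' @examples
#' m <- ontogeny_piecewise3(107.8, 88.6, 1.83, 370.1, 6.99, 12.6, 445.2,
#'                          enzyme = "SULT1A1")
#' evaluate_abundance(m, c(0, 5, 20))
ontogeny_piecewise3 <- function(intercept1, slope1, breakpoint1,
                                anchor2, slope2, breakpoint2,
                                plateau, enzyme = NULL) {
  vals <- c(intercept1 = intercept1, slope1 = slope1,
            breakpoint1 = breakpoint1, anchor2 = anchor2, slope2 = slope2,
            breakpoint2 = breakpoint2, plateau = plateau)
  if (any(!is.finite(vals))) stop("all parameters must be finite")
  if (!(breakpoint1 > 0 && breakpoint2 > breakpoint1)) {
    stop("breakpoints must satisfy 0 < breakpoint1 < breakpoint2")
  }
  if (plateau <= 0) stop("`plateau` must be positive")
  structure(as.list(vals), enzyme = enzyme,
            class = c("ontogeny_piecewise3", "ontogeny_model"))
}

#' Constant (age-invariant) ontogeny profile
#'
#' @param plateau the constant abundance or relative-activity level.
#' @param enzyme optional enzyme label.
#' @return An object of class `c("ontogeny_constant", "ontogeny_model")`;
#'   its relative activity is identically 1 at every age.
#' @export
ontogeny_constant <- function(plateau = 1, enzyme = NULL) {
  if (!is.finite(plateau) || plateau <= 0) stop("`plateau` must be positive")
  structure(list(plateau = plateau), enzyme = enzyme,
            class = c("ontogeny_constant", "ontogeny_model"))
}

#' Evaluate enzyme abundance at a given age
#'
#' @param model an `ontogeny_model`.
#' @param age postnatal age in years (vectorised, must be `>= 0`).
#' @return Abundance in the model's units (pmol/mg cytosolic protein for
#'   the built-in SULT models).
#' @export
evaluate_abundance <- function(model, age) {
  UseMethod("evaluate_abundance")
}

#' @export
evaluate_abundance.ontogeny_piecewise3 <- function(model, age) {
  stop_if_negative_age(age)
  with(model, ifelse(age < breakpoint1,
                     intercept1 + slope1 * age,
                     ifelse(age <= breakpoint2,
                            anchor2 + slope2 * (age - breakpoint1),
                            plateau)))
}

#' @export
evaluate_abundance.ontogeny_constant <- function(model, age) {
  stop_if_negative_age(age)
  rep(model$plateau, length(age))
}

#' Relative enzyme activity (ratio to a reference age)
#'
#' Converts an abundance-vs-age model into the dimensionless multiplier
#' applied to adult in vitro Vmax values: the ratio of abundance at `age`
#' to abundance at `reference_age`.  The default reference age of 20 years
#' lies on the adult plateau of every built-in model, matching the adult
#' tissue from which in vitro kinetic constants are derived.
#'
#' @inheritParams evaluate_abundance
#' @param reference_age age whose abundance defines the denominator.
#' @return Dimensionless fraction; exactly 1 at `age == reference_age`.
#' @export
relative_activity <- function(model, age, reference_age = 20) {
  UseMethod("relative_activity")
}

#' @export
relative_activity.ontogeny_constant <- function(model, age, reference_age = 20) {
  stop_if_negative_age(age)
  rep(1, length(age))
}

#' @export
relative_activity.ontogeny_model <- function(model, age, reference_age = 20) {
  ref <- evaluate_abundance(model, reference_age)
  if (ref <= 0) stop("abundance at the reference age must be positive")
  evaluate_abundance(model, age) / ref
}

#' @export
print.ontogeny_model <- function(x, ...) {
  enz <- attr(x, "enzyme")
  cat(sprintf("<%s>%s\n", class(x)[1],
              if (!is.null(enz)) paste0(" ", enz) else ""))
  cat("  ", paste(sprintf("%s = %g", names(x), unlist(x)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Built-in SULT ontogeny model library
#'
#' Returns the fitted three-phase piecewise abundance models for SULT1A1,
#' SULT1A3, SULT2A1 and SULT1B1 (abundance in pmol/mg cytosolic protein as
#' a function of postnatal age in years, derived from liver proteomic
#' abundance data), plus a constant profile for SULT1E1, for which no
#' age dependence is assumed.
#'
#' SULT1A1 abundance starts at roughly a quarter of the adult level and
#' rises steeply over the first two years; SULT1A3 is highest at birth and
#' declines; SULT2A1 rises sharply in infancy, overshoots, and settles to
#' its adult plateau; SULT1B1 matures over early childhood.  SULT1B1 is
#' carried for completeness even though acetaminophen has no SULT1B1
#' pathway.
#'
#' @return Named list of `ontogeny_model` objects
#'   (`SULT1A1`, `SULT1A3`, `SULT2A1`, `SULT1B1`, `SULT1E1`).
#' @export
#' @examples
#' lib <- builtin_ontogeny_library()
#' evaluate_abundance(lib$SULT1A1, 0)    # 107.8 pmol/mg at birth
#' relative_activity(lib$SULT1A1, 0)     # ~24% of adult
builtin_ontogeny_library <- function() {
  list(
    SULT1A1 = ontogeny_piecewise3(107.8, 88.6, 1.83, 370.1, 6.99, 12.6,
                                  445.2, enzyme = "SULT1A1"),
    SULT1A3 = ontogeny_piecewise3(117.3, -28.7, 2, 60, 5.66, 8.6,
                                  97.2, enzyme = "SULT1A3"),
    SULT2A1 = ontogeny_piecewise3(705.3, 975.2, 1.2, 1893, -65.5, 13.2,
                                  1095, enzyme = "SULT2A1"),
    SULT1B1 = ontogeny_piecewise3(45.5, 37.3, 2.6, 140.6, -4.69, 8.1,
                                  115, enzyme = "SULT1B1"),
    SULT1E1 = ontogeny_constant(1, enzyme = "SULT1E1")
  )
}
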