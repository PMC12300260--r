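# In vitro-in vivo extrapolation: scale per-mg-protein Michaelis-Menten
# kinetics into age- and concentration-dependent whole-organ clearances,
# and decompose total systemic clearance into pathway fractions (fm).

UL_PER_MIN_TO_L_PER_H <- 60 / 1e6

# Linear (Cu = 0) per-pathway intrinsic clearance in L/h for a kinetics
# table, given system parameters, ontogeny multipliers and scalars.
# Returns a named numeric vector ordered as `kin$pathway`.
linear_clint_vector <- function(kin, age, sys, ont, active_scalar = 1,
                                calibration = 1, multipliers = NULL) {
  rel <- vapply(kin$pathway, function(pw)
    pathway_relative_activity(ont, pw, age), numeric(1))
  mult <- rep(1, nrow(kin))
  if (!is.null(multipliers)) {
    idx <- match(kin$pathway, names(multipliers))
    mult <- ifelse(is.na(idx), 1, as.numeric(multipliers)[idx])
  }
  ppgl <- ifelse(kin$pool == "cytosolic", sys$cppgl, sys$mppgl)
  per_mg <- kin$vmax / kin$km                 # uL/min/mg at Cu = 0
  setNames(per_mg * rel * mult * ppgl * sys$liver_weight * active_scalar *
             calibration * UL_PER_MIN_TO_L_PER_H,
           kin$pathway)
}

#' Hepatic intrinsic clearance of a single pathway
#'
#' Scales an in vitro Michaelis-Menten pathway to whole-liver intrinsic
#' clearance at a given age and unbound plasma concentration:
#' `CLint = vmax * activity(age) / (km + Cu) * PPGL * liver_weight *
#' active_scalar`, converted from uL/min to L/h.  `PPGL` is the microsomal
#' or cytosolic protein-per-gram-liver scalar matching the pathway's
#' protein pool.  Saturation is evaluated at the unbound plasma
#' concentration (well-stirred approximation).
#'
#' @param kin one-row kinetics data frame (columns `pathway`, `vmax`
#'   pmol/min/mg, `km` uM, `pool`) as held in
#'   `load_compound()$kinetics`.
#' @param age postnatal age in years.
#' @param unbound_conc unbound plasma concentration in mg/L (>= 0).
#' @param sys [system_parameters()] at the same age.
#' @param ont an [enzyme_ontogeny_table()].
#' @param mw molecular weight (g/mol), used to express `km` on the mg/L
#'   scale.
#' @param active_scalar empirical multiplier on hepatic intrinsic
#'   clearance (1.5 for the packaged acetaminophen profile).
#' @param calibration optional global in vitro-in vivo calibration factor
#'   (see [apap_model()]).
#' @return Intrinsic clearance in L/h.
#' @export
#' @examples
#' sys <- system_parameters(20)
#' ont <- enzyme_ontogeny_table()
#' kin <- load_compound()$kinetics
#' pathway_clint(kin[kin$pathway == "SULT1A1", ], 20, 0, sys, ont, 151.2)
pathway_clint <- function(kin, age, unbound_conc = 0, sys, ont, mw,
                          active_scalar = 1, calibration = 1) {
  stopifnot(nrow(kin) == 1L, unbound_conc >= 0)
  km_mass <- km_mass_units(kin$km, mw)
  s0 <- linear_clint_vector(kin, age, sys, ont, active_scalar, calibration)
  unname(s0 * km_mass / (km_mass + unbound_conc))
}

#' Well-stirred hepatic clearance
#'
#' `CLh = Qh * fuB * CLint / (Qh + fuB * CLint)` with
#' `fuB = fu / blood_plasma_ratio`; the liver is treated as a single
#' well-mixed compartment, so hepatic clearance is bounded above by
#' hepatic blood flow.
#'
#' @param total_clint total hepatic intrinsic clearance (L/h, >= 0).
#' @param sys [system_parameters()] (supplies `hepatic_blood_flow`).
#' @param fu fraction unbound in plasma.
#' @param bp blood-to-plasma concentration ratio.
#' @return Hepatic clearance in L/h.
#' @export
hepatic_clearance <- function(total_clint, sys, fu = sys$fu_plasma,
                              bp = sys$blood_plasma_ratio) {
  stopifnot(total_clint >= 0)
  fub <- fu / bp
  qh <- sys$hepatic_blood_flow
  qh * fub * total_clint / (qh + fub * total_clint)
}

# Renal clearance at a given age: the adult value scaled by the GFR
# maturation fraction and linear body-weight fraction (filtration-
# dominated elimination).
renal_clearance <- function(cl_renal_adult, sys) {
  cl_renal_adult * sys$gfr_fraction * sys$body_weight / 70
}

#' Assemble a PBPK model context
#'
#' Bundles a compound profile, physiology configuration and enzyme
#' ontogeny table, and (by default) anchors the in vitro-in vivo
#' extrapolation by solving for the single global calibration factor on
#' total hepatic intrinsic clearance that makes the predicted adult
#' systemic clearance (well-stirred hepatic + renal, linear range) equal
#' the compound's reference IV clearance.  Calibrating the IVIVE chain to
#' an observed adult IV clearance is standard practice when the absolute
#' protein scalars of the system model and of the in vitro assays cannot
#' be reconciled; pathway contribution fractions are invariant to this
#' uniform rescaling.
#'
#' @param profile a [load_compound()] result.
#' @param physiology a [physiology_defaults()] configuration.
#' @param ontogeny an [enzyme_ontogeny_table()].
#' @param calibrate logical; solve for the adult-clearance calibration
#'   factor (default `TRUE`).  With `FALSE` the factor is 1.
#' @return Object of class `pbpk_model`.
#' @export
#' @examples
#' model <- apap_model()
#' model$calibration
apap_model <- function(profile = load_compound(),
                       physiology = physiology_defaults(),
                       ontogeny = enzyme_ontogeny_table(physiology),
                       calibrate = TRUE) {
  stopifnot(inherits(profile, "compound_profile"))
  model <- structure(list(profile = profile, physiology = physiology,
                          ontogeny = ontogeny, calibration = 1),
                     class = "pbpk_model")
  if (calibrate) {
    adult_age <- physiology$adult_age
    sys <- system_parameters(adult_age, physiology)
    raw <- sum(linear_clint_vector(profile$kinetics, adult_age, sys,
                                   ontogeny,
                                   profile$active_hepatic_scalar, 1))
    clr <- renal_clearance(profile$cl_renal_adult_l_per_h, sys)
    clh_target <- profile$cl_iv_reference_l_per_h - clr
    qh <- sys$hepatic_blood_flow
    if (clh_target <= 0 || clh_target >= qh) {
      stop("reference IV clearance is not attainable with the configured ",
           "hepatic blood flow")
    }
    fub <- sys$fu_plasma / sys$blood_plasma_ratio
    clint_req <- qh * clh_target / (fub * (qh - clh_target))
    model$calibration <- clint_req / raw
  }
  model
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat(sprintf("<pbpk_model> %s; IVIVE calibration factor %.3f\n",
              x$profile$name, x$calibration))
  invisible(x)
}

# Per-subject clearance context: everything the ODE right-hand side needs.
clearance_context <- function(model, age, body_weight = NULL,
                              multipliers = NULL) {
  sys <- system_parameters(age, model$physiology, body_weight)
  kin <- model$profile$kinetics
  s0 <- linear_clint_vector(kin, age, sys, model$ontogeny,
                            model$profile$active_hepatic_scalar,
                            model$calibration, multipliers)
  list(sys = sys,
       pathways = kin$pathway,
       s0 = s0,
       km_mass = km_mass_units(kin$km, model$profile$molecular_weight),
       fu = model$profile$fu_plasma,
       bp = model$profile$blood_plasma_ratio,
       clr = renal_clearance(model$profile$cl_renal_adult_l_per_h, sys))
}

# Concentration-dependent clearances from a context; conc in mg/L plasma.
context_clearances <- function(ctx, conc = 0) {
  cu <- ctx$fu * conc
  clint <- ctx$s0 * ctx$km_mass / (ctx$km_mass + cu)
  clh <- hepatic_clearance(sum(clint), ctx$sys, ctx$fu, ctx$bp)
  list(clint = clint, clh = clh, clr = ctx$clr, total = clh + ctx$clr)
}

#' Pathway contribution breakdown (fm)
#'
#' Decomposes total systemic clearance at a given age into per-pathway
#' fractions: each hepatic pathway's share of hepatic clearance is its
#' share of total hepatic intrinsic clearance, and renal excretion
#' contributes `CLr / (CLh + CLr)`.  Fractions sum to 1.  By default the
#' breakdown is evaluated in the linear range (`conc = 0`).
#'
#' @param model an [apap_model()].
#' @param age postnatal age in years.
#' @param conc total plasma concentration (mg/L) at which to evaluate
#'   saturable kinetics; 0 for the linear range.
#' @return Data frame with columns `pathway`, `clint` (L/h; `NA` for the
#'   renal row), `clearance` (L/h of systemic clearance attributed to the
#'   pathway) and `fm`; attributes `clh`, `clr`, `total_clearance`, `age`.
#' @export
#' @examples
#' fm <- fm_breakdown(apap_model(), age = 7 / 365.25)   # one-week neonate
#' sum(fm$fm)   # 1
fm_breakdown <- function(model, age, conc = 0) {
  stopifnot(inherits(model, "pbpk_model"))
  ctx <- clearance_context(model, age)
  cl <- context_clearances(ctx, conc)
  hep_share <- cl$clint / sum(cl$clint)
  out <- data.frame(
    pathway = c(ctx$pathways, "renal"),
    clint = c(unname(cl$clint), NA_real_),
    clearance = c(unname(hep_share) * cl$clh, cl$clr)
  )
  out$fm <- out$clearance / cl$total
  attr(out, "clh") <- cl$clh
  attr(out, "clr") <- cl$clr
  attr(out, "total_clearance") <- cl$total
  attr(out, "age") <- age
  out
}

# Summed fm over a pathway family ("SULT", "UGT", "CYP", "renal" or a
# specific pathway name).
fm_family <- function(breakdown, family) {
  if (family %in% breakdown$pathway) {
    return(breakdown$fm[breakdown$pathway == family])
  }
  sum(breakdown$fm[startsWith(breakdown$pathway, family)])
}
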