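# Age-dependent system parameters and non-SULT enzyme maturation profiles.
#
# Commercial population simulators carry proprietary virtual-individual
# covariate machinery; this module substitutes documented published
# equations (growth-reference splines, BSA-based liver allometry,
# allometric hepatic flow, the standard microsomal-protein age equation and
# a sigmoidal GFR maturation curve), all parameterised in a single YAML
# configuration shipped with the package.

.physio_cache <- new.env(parent = emptyenv())

#' Default physiology configuration
#'
#' Reads (and caches) the packaged `physiology-defaults.yaml`, which holds
#' every constant of the age-resolved physiology: growth anchors, liver
#' allometry, hepatic flow, protein-per-gram-liver scalars, GFR maturation,
#' plasma binding, the non-SULT enzyme maturation profiles and the
#' inter-individual variability defaults.
#'
#' @param path optional path to an alternative YAML file.
#' @return Named list (the parsed configuration).
#' @export
physiology_defaults <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "physiology-defaults.yaml",
                        package = "sultpbpk")
    key <- "defaults"
    if (!is.null(.physio_cache[[key]])) return(.physio_cache[[key]])
    cfg <- yaml::read_yaml(path)
    .physio_cache[[key]] <- cfg
    return(cfg)
  }
  yaml::read_yaml(path)
}

growth_interp <- function(cfg) {
  g <- cfg$growth
  list(weight = splinefun(g$ages, g$weights, method = "hyman"),
       height = splinefun(g$ages, g$heights, method = "hyman"))
}

body_weight_for_age <- function(age, cfg = physiology_defaults()) {
  a <- pmin(age, cfg$adult_age)
  growth_interp(cfg)$weight(a)
}

haycock_bsa <- function(weight_kg, height_cm) {
  0.024265 * weight_kg^0.5378 * height_cm^0.3964
}

mppgl_for_age <- function(age, cfg = physiology_defaults()) {
  a <- pmin(age, cfg$adult_age)
  co <- cfg$mppgl$log10_coefficients
  10^(co[1] + co[2] * a + co[3] * a^2 + co[4] * a^3)
}

gfr_fraction_for_age <- function(age, cfg = physiology_defaults()) {
  g <- cfg$gfr
  pma <- g$pma_at_birth_weeks + age * 365.25 / 7
  pma^g$hill / (pma^g$hill + g$tm50_weeks^g$hill)
}

#' Age-resolved system parameters
#'
#' Computes the physiological inputs of the minimal PBPK model at a given
#' postnatal age: body and liver weight, hepatic blood flow, microsomal and
#' cytosolic protein per gram of liver (MPPGL/CPPGL), the GFR maturation
#' fraction (adult = 1) and plasma binding constants.  Physiology is
#' age-invariant above the configured adult age (20 years by default).
#'
#' @param age postnatal age in years (scalar, `0 <= age <= 100`).
#' @param config physiology configuration, see [physiology_defaults()].
#' @param body_weight optional realised body weight (kg) of an individual
#'   subject; liver weight, hepatic flow and downstream renal scaling are
#'   rescaled from the growth-model weight at that age.
#' @return List of class `system_parameters` with elements `age`,
#'   `body_weight` (kg), `height` (cm), `liver_weight` (g),
#'   `hepatic_blood_flow` (L/h), `mppgl` and `cppgl` (mg/g),
#'   `gfr_fraction`, `fu_plasma`, `blood_plasma_ratio`.
#' @export
#' @examples
#' system_parameters(0.02)   # a one-week-old neonate
#' system_parameters(20)     # adult reference
system_parameters <- function(age, config = physiology_defaults(),
                              body_weight = NULL) {
  stopifnot(length(age) == 1L)
  stop_if_negative_age(age)
  if (age > 100) stop("`age` must be <= 100 years")
  interp <- growth_interp(config)
  a <- pmin(age, config$adult_age)
  bw_model <- interp$weight(a)
  ht <- interp$height(a)
  bw <- body_weight %||% bw_model
  if (bw <= 0) stop("`body_weight` must be positive")
  size_ratio <- bw / bw_model
  bsa <- haycock_bsa(bw_model, ht) # growth-reference BSA
  liver <- config$liver$bsa_coefficient * bsa^config$liver$bsa_exponent *
    size_ratio
  qh <- config$hepatic_flow$adult_l_per_h *
    (bw / 70)^config$hepatic_flow$allometric_exponent
  structure(list(
    age = age,
    body_weight = bw,
    height = ht,
    liver_weight = liver,
    hepatic_blood_flow = qh,
    mppgl = mppgl_for_age(a, config),
    cppgl = config$cppgl,
    gfr_fraction = gfr_fraction_for_age(a, config),
    fu_plasma = config$fu_plasma,
    blood_plasma_ratio = config$blood_plasma_ratio
  ), class = "system_parameters")
}

maturation_fraction <- function(age, f0, t50, hill) {
  f0 + (1 - f0) * age^hill / (t50^hill + age^hill)
}

#' Enzyme ontogeny table for all metabolic pathways
#'
#' Assembles the per-pathway relative-activity profiles used by the IVIVE
#' layer: SULT pathways delegate to the abundance-based ontogeny models in
#' `sult_library`; UGT and CYP pathways use the configured sigmoidal
#' maturation profiles, normalised to 1 at the adult reference age.
#'
#' @param config physiology configuration ([physiology_defaults()]).
#' @param sult_library named list of `ontogeny_model` objects; defaults to
#'   [builtin_ontogeny_library()].
#' @param reference_age adult reference age (years) at which every profile
#'   equals 1.
#' @return Object of class `enzyme_ontogeny_table`.
#' @export
enzyme_ontogeny_table <- function(config = physiology_defaults(),
                                  sult_library = builtin_ontogeny_library(),
                                  reference_age = 20) {
  entries <- list()
  for (enz in names(sult_library)) {
    entries[[enz]] <- list(type = "sult", model = sult_library[[enz]])
  }
  for (pw in names(config$maturation)) {
    m <- config$maturation[[pw]]
    entries[[pw]] <- list(type = "maturation", f0 = m$f0, t50 = m$t50,
                          hill = m$hill)
  }
  structure(list(entries = entries, reference_age = reference_age),
            class = "enzyme_ontogeny_table")
}

#' Relative pathway activity at a given age
#'
#' @param table an [enzyme_ontogeny_table()].
#' @param pathway pathway identifier (e.g. `"SULT1A1"`, `"UGT1A9"`,
#'   `"CYP2E1"`).
#' @param age postnatal age in years (vectorised).
#' @return Dimensionless fraction-of-adult activity (1 at the reference
#'   age).
#' @export
pathway_relative_activity <- function(table, pathway, age) {
  stopifnot(inherits(table, "enzyme_ontogeny_table"))
  stop_if_negative_age(age)
  e <- table$entries[[pathway]]
  if (is.null(e)) stop("unknown pathway: ", pathway)
  # activity is taken as fully mature at and beyond the adult reference age
  a <- pmin(age, table$reference_age)
  if (e$type == "sult") {
    relative_activity(e$model, a, reference_age = table$reference_age)
  } else {
    maturation_fraction(a, e$f0, e$t50, e$hill) /
      maturation_fraction(table$reference_age, e$f0, e$t50, e$hill)
  }
}

#' @export
print.enzyme_ontogeny_table <- function(x, ...) {
  cat("<enzyme_ontogeny_table> pathways:",
      paste(names(x$entries), collapse = ", "), "\n")
  invisible(x)
}
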