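# Compound profile: validated container for the acetaminophen parameter
# set (physicochemistry, binding, distribution, per-pathway
# Michaelis-Menten kinetics and reference clearances).

apap_pathways <- function() {
  c("UGT1A1", "UGT1A9", "UGT2B15",
    "SULT1A1", "SULT1A3", "SULT1E1", "SULT2A1",
    "CYP1A2", "CYP2C9", "CYP2C19", "CYP2D6", "CYP2E1", "CYP3A4")
}

validate_compound <- function(p) {
  req <- c("name", "molecular_weight", "fu_plasma", "blood_plasma_ratio",
           "vss_l_per_kg", "cl_iv_reference_l_per_h",
           "cl_renal_adult_l_per_h", "active_hepatic_scalar", "kinetics")
  missing <- setdiff(req, names(p))
  if (length(missing)) {
    stop("compound profile is missing fields: ",
         paste(missing, collapse = ", "))
  }
  if (!(p$fu_plasma > 0 && p$fu_plasma <= 1)) {
    stop("fu_plasma must lie in (0, 1]")
  }
  if (p$vss_l_per_kg <= 0) stop("vss_l_per_kg must be positive")
  kin <- p$kinetics
  if (any(kin$vmax <= 0) || any(kin$km <= 0)) {
    stop("all vmax and km values must be positive")
  }
  if (!all(kin$pool %in% c("microsomal", "cytosolic"))) {
    stop("pathway pool must be 'microsomal' or 'cytosolic'")
  }
  bad_pool <- (grepl("^SULT", kin$pathway) & kin$pool != "cytosolic") |
    (grepl("^(CYP|UGT)", kin$pathway) & kin$pool != "microsomal")
  if (any(bad_pool)) {
    stop("SULT pathways must be cytosolic and CYP/UGT microsomal: ",
         paste(kin$pathway[bad_pool], collapse = ", "))
  }
  unknown <- setdiff(kin$pathway, apap_pathways())
  if (length(unknown)) {
    stop("unknown pathway name(s): ", paste(unknown, collapse = ", "))
  }
  if (p$name == "acetaminophen" &&
      !setequal(kin$pathway, apap_pathways())) {
    stop("the acetaminophen profile must carry exactly the 13 known ",
         "elimination pathways")
  }
  invisible(p)
}

#' Load a compound profile
#'
#' Reads a compound definition from YAML or JSON and validates it.  With no
#' arguments the packaged acetaminophen profile is returned: molecular
#' weight 151.2 g/mol, fu 0.82, blood:plasma ratio 1, Vss 0.8 L/kg,
#' reference IV clearance 19.7 L/h, adult renal clearance 1.12 L/h, an
#' active hepatic scalar of 1.5 applied to total intrinsic clearance, and
#' Michaelis-Menten constants for 3 UGT, 4 SULT and 6 CYP pathways.
#'
#' @param path path to a YAML (or JSON) compound file; `NULL` loads the
#'   packaged acetaminophen profile.
#' @return Object of class `compound_profile`; element `kinetics` is a
#'   data frame with columns `pathway`, `vmax` (pmol/min/mg pool protein),
#'   `km` (uM) and `pool` (`microsomal`/`cytosolic`).
#' @export
#' @examples
#' prof <- load_compound()
#' nrow(prof$kinetics)                 # 13 pathways
#' prof$cl_iv_reference_l_per_h       # 19.7
load_compound <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "apap.yaml", package = "sultpbpk")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  kin <- raw$pathways
  if (is.null(kin)) stop("compound profile is missing fields: pathways")
  if (!is.data.frame(kin)) {
    kin <- do.call(rbind, lapply(kin, function(r) {
      data.frame(pathway = r$pathway, vmax = as.numeric(r$vmax),
                 km = as.numeric(r$km), pool = r$pool)
    }))
  }
  kin$vmax <- as.numeric(kin$vmax)
  kin$km <- as.numeric(kin$km)
  prof <- raw
  prof$pathways <- NULL
  prof$kinetics <- kin
  # numeric scalars as doubles regardless of the serialization format
  for (f in names(prof)) {
    if (is.integer(prof[[f]])) prof[[f]] <- as.numeric(prof[[f]])
  }
  class(prof) <- "compound_profile"
  validate_compound(prof)
  prof
}

#' @export
print.compound_profile <- function(x, ...) {
  cat(sprintf("<compound_profile> %s (MW %.1f, fu %.2f, Vss %.2f L/kg)\n",
              x$name, x$molecular_weight, x$fu_plasma, x$vss_l_per_kg))
  cat(sprintf("  %d elimination pathways; reference CL_iv %.1f L/h\n",
              nrow(x$kinetics), x$cl_iv_reference_l_per_h))
  invisible(x)
}

#' Serialize a compound profile to JSON
#'
#' Round-trips through [load_compound()] with full numeric precision.
#'
#' @param profile a `compound_profile`.
#' @param path output file path (`.json`).
#' @export
write_compound <- function(profile, path) {
  stopifnot(inherits(profile, "compound_profile"))
  out <- unclass(profile)
  out$pathways <- out$kinetics
  out$kinetics <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Convert a Michaelis constant from molar to mass-concentration units
#'
#' Bridges in vitro Km values (uM) to the plasma concentration scale of the
#' simulation (mg/L): `km_mass = km_um * mw / 1000`.
#'
#' @param km_um Michaelis constant in uM.
#' @param mw molecular weight in g/mol.
#' @return Km in mg/L.
#' @export
#' @examples
#' km_mass_units(2400, 151.2)   # SULT1A1: 362.9 mg/L
km_mass_units <- function(km_um, mw) {
  stopifnot(km_um > 0, mw > 0)
  km_um * mw / 1000
}
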