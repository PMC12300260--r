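# Synthetic data generation: abundance-vs-age datasets with the
# statistical structure of liver proteomic ontogeny studies, and virtual
# pediatric cohorts for population simulation.

#' Pediatric age-group definitions
#'
#' Clinical age windows used throughout the package: neonates
#' (birth-28 days), infants (29 days-2 years), children (2-12 years) and a
#' healthy adult window (20-50 years).  `rep_age` is the representative
#' (mid-window) age used for deterministic single-subject analyses, and
#' `interval_h` the default dosing interval of the multiple-dose IV
#' regimen for the group.
#'
#' @return Data frame with columns `group`, `min_age`, `max_age`,
#'   `rep_age` (years) and `interval_h`.
#' @export
age_groups <- function() {
  data.frame(
    group = c("neonate", "infant", "child", "adult"),
    min_age = c(0, 29 / 365.25, 2, 20),
    max_age = c(28 / 365.25, 2, 12, 50),
    rep_age = c(14 / 365.25, (29 / 365.25 + 2) / 2, 7, 30),
    interval_h = c(4, 4, 6, NA)
  )
}

age_group_row <- function(group) {
  g <- age_groups()
  row <- g[g$group == group, ]
  if (nrow(row) != 1L) {
    stop("unknown age group: ", group,
         " (expected one of ", paste(g$group, collapse = ", "), ")")
  }
  row
}

# Default age sampler for abundance datasets: 70% pediatric ages uniform
# over 0-18 years (mirroring the pediatric-rich design of liver ontogeny
# tissue banks), 30% adults uniform on 18-60.  Together with the default
# noise CV of 0.6 this design reproduces the weak-R^2 regime (refit
# R^2 ~ 0.1-0.2) characteristic of individual-level enzyme-abundance data.
default_age_sampler <- function(n) {
  ped <- runif(n) < 0.7
  age <- numeric(n)
  age[ped] <- runif(sum(ped), 0, 18)
  age[!ped] <- runif(sum(!ped), 18, 60)
  age
}

#' Simulate an abundance-versus-age dataset
#'
#' Draws individual abundance observations around a known ontogeny curve
#' with multiplicative log-normal inter-individual noise:
#' `abundance_i = truth(age_i) * exp(eps_i)` with
#' `eps_i ~ N(0, sigma^2)`, `sigma = sqrt(log(1 + cv^2))`, so the median
#' of `simulated / truth` is 1.  The default noise CV of 0.6 reproduces
#' the weak coefficient-of-determination regime (refit R^2 of roughly
#' 0.1-0.2) that is characteristic of pediatric enzyme-abundance data.
#'
#' @param truth an `ontogeny_model` generating the mean curve.
#' @param n_subjects number of observations.
#' @param noise_cv log-normal coefficient of variation (>= 0).
#' @param seed integer seed (optional); the caller's RNG stream is not
#'   disturbed.
#' @param enzyme enzyme label written into the output.
#' @param age_sampler function `n -> ages`; defaults to 70% pediatric ages
#'   uniform on 0-18 years and 30% adults uniform on 18-60 years.
#' @return Data frame with columns `enzyme`, `age_years`,
#'   `abundance_pmol_per_mg` (the abundance CSV dialect accepted by
#'   [fit_ontogeny()]).
#' @export
#' @examples
#' lib <- builtin_ontogeny_library()
#' d <- simulate_abundance_dataset(lib$SULT1A1, 50, noise_cv = 0.6, seed = 1)
simulate_abundance_dataset <- function(truth, n_subjects, noise_cv = 0.6,
                                       seed = NULL, enzyme = NULL,
                                       age_sampler = default_age_sampler) {
  stopifnot(inherits(truth, "ontogeny_model"),
            n_subjects >= 1, noise_cv >= 0)
  enzyme <- enzyme %||% (attr(truth, "enzyme") %||% "enzyme")
  with_seed(seed, {
    age <- age_sampler(n_subjects)
    sigma <- sqrt(log(1 + noise_cv^2))
    eps <- if (noise_cv > 0) rnorm(n_subjects, 0, sigma) else rep(0, n_subjects)
    data.frame(enzyme = enzyme, age_years = age,
               abundance_pmol_per_mg = evaluate_abundance(truth, age) *
                 exp(eps))
  })
}

#' Sample a virtual cohort
#'
#' Draws virtual subjects for an age group: ages uniform within the group
#' window, body weight log-normally distributed around the growth-model
#' weight at each subject's age, and per-pathway intrinsic-clearance and
#' Vss multipliers drawn log-normally with mean 1 (so the population
#' average of each scaled parameter equals its typical-subject value).
#'
#' @param age_group one of `"neonate"`, `"infant"`, `"child"`, `"adult"`.
#' @param n number of subjects (>= 1).
#' @param seed integer seed (optional).
#' @param config physiology configuration supplying the variability CVs
#'   (`enzyme_cv`, `vss_cv`, `weight_cv`); see [physiology_defaults()].
#' @param enzyme_cv,vss_cv,weight_cv optional overrides of the configured
#'   coefficients of variation (set all to 0 for identical subjects).
#' @return Data frame with columns `id`, `group`, `age` (years),
#'   `body_weight` (kg), `vss_mult` and one `mult.<pathway>` column per
#'   elimination pathway.
#' @export
sample_cohort <- function(age_group, n, seed = NULL,
                          config = physiology_defaults(),
                          enzyme_cv = NULL, vss_cv = NULL,
                          weight_cv = NULL) {
  stopifnot(n >= 1)
  row <- age_group_row(age_group)
  enzyme_cv <- enzyme_cv %||% config$variability$enzyme_cv
  vss_cv <- vss_cv %||% config$variability$vss_cv
  weight_cv <- weight_cv %||% config$variability$weight_cv
  lnorm_mult <- function(n, cv) {
    if (cv <= 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + cv^2))
    rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean 1
  }
  with_seed(seed, {
    age <- runif(n, row$min_age, row$max_age)
    bw <- body_weight_for_age(age, config) * lnorm_mult(n, weight_cv)
    out <- data.frame(id = seq_len(n), group = age_group, age = age,
                      body_weight = bw, vss_mult = lnorm_mult(n, vss_cv))
    for (pw in apap_pathways()) {
      out[[paste0("mult.", pw)]] <- lnorm_mult(n, enzyme_cv)
    }
    out
  })
}

subject_multipliers <- function(subject) {
  cols <- grep("^mult\\.", names(subject), value = TRUE)
  setNames(as.numeric(subject[1, cols]), sub("^mult\\.", "", cols))
}
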