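# File-based entry points tying the analysis stages together: ontogeny
# fitting from an abundance CSV, population verification reports, and
# pathway-fraction (fm) reports.  Outputs are deterministic given the
# configuration and seed.

#' Fit ontogeny models to an abundance CSV and write the results
#'
#' Reads abundance records (columns `enzyme`, `age_years`,
#' `abundance_pmol_per_mg`), fits the requested candidate forms per enzyme,
#' selects the best by AIC, and writes a per-form fit-statistics CSV and a
#' JSON file of the selected models.
#'
#' @param input_csv path to the abundance CSV.
#' @param output_dir directory for outputs (created if needed).
#' @param forms candidate forms to fit (subset of [ontogeny_forms()]).
#' @return Invisibly, a list with `fits` (data frame of per-enzyme,
#'   per-form statistics) and `selected` (named list of winning
#'   `ontogeny_fit` objects); side effect: writes
#'   `ontogeny-fit-statistics.csv` and `ontogeny-models.json` in
#'   `output_dir`.
#' @export
run_ontogeny_fit <- function(input_csv, output_dir,
                             forms = ontogeny_forms()) {
  forms <- match.arg(forms, several.ok = TRUE)
  records <- read.csv(input_csv, stringsAsFactors = FALSE)
  if (nrow(records) == 0) stop("abundance CSV is empty: ", input_csv)
  if (!"enzyme" %in% names(records)) records$enzyme <- "enzyme"
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stats_rows <- list()
  selected <- list()
  for (enz in unique(records$enzyme)) {
    sub <- records[records$enzyme == enz, ]
    fits <- lapply(forms, function(f) fit_ontogeny(sub, f))
    for (fit in fits) {
      stats_rows[[length(stats_rows) + 1L]] <- data.frame(
        enzyme = enz, form = fit$form, npar = fit$npar, n = fit$n,
        rss = fit$rss, aic = fit$aic, r2 = fit$r2,
        converged = fit$converged)
    }
    selected[[enz]] <- select_best(fits)
  }
  stats_df <- do.call(rbind, stats_rows)
  write.csv(stats_df, file.path(output_dir, "ontogeny-fit-statistics.csv"),
            row.names = FALSE)
  models_json <- lapply(selected, function(fit) {
    list(form = fit$form, params = as.list(fit$params), rss = fit$rss,
         aic = fit$aic, r2 = fit$r2, n = fit$n, converged = fit$converged)
  })
  jsonlite::write_json(models_json,
                       file.path(output_dir, "ontogeny-models.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(fits = stats_df, selected = selected))
}

#' Run the full verification experiment and write the report
#'
#' Runs [adult_verification()] and [pediatric_verification()], joins the
#' predictions with [observed_exposure()] via [verification_report()] and
#' writes the combined report CSV.
#'
#' @param output_dir directory for `verification-report.csv`.
#' @param seed integer seed governing all cohort sampling.
#' @param model an [apap_model()].
#' @param adult_n adult subjects per dose level.
#' @param trials pediatric trials per group.
#' @return Invisibly, the report data frame.
#' @export
run_verification <- function(output_dir, seed = 1L, model = apap_model(),
                             adult_n = 100, trials = 10) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  adult <- adult_verification(model, n = adult_n, seed = child_seed(seed, 1))
  ped <- pediatric_verification(model, seed = child_seed(seed, 2),
                                trials = trials)
  shared <- c("population", "dose_mg_per_kg", "parameter", "predicted")
  predicted <- rbind(adult[, shared], ped[, shared])
  report <- verification_report(predicted)
  report$seed <- seed
  write.csv(report, file.path(output_dir, "verification-report.csv"),
            row.names = FALSE)
  invisible(report)
}

#' Pathway-fraction report across ages
#'
#' Computes the linear-range clearance breakdown at each requested age and
#' writes/returns a long-format table of pathway fractions, plus the
#' family totals (SULT, UGT, CYP, renal).
#'
#' @param ages ages in years.
#' @param file optional CSV output path.
#' @param model an [apap_model()].
#' @return Data frame with columns `age`, `pathway`, `fm`.
#' @export
#' @examples
#' run_fm_report(c(7 / 365.25, 1, 7, 25))
run_fm_report <- function(ages, file = NULL, model = apap_model()) {
  rows <- lapply(ages, function(a) {
    bd <- fm_breakdown(model, a)
    fam <- data.frame(
      pathway = c("SULT_total", "UGT_total", "CYP_total"),
      clint = NA_real_, clearance = NA_real_,
      fm = c(fm_family(bd, "SULT"), fm_family(bd, "UGT"),
             fm_family(bd, "CYP")))
    out <- rbind(bd, fam)
    data.frame(age = a, pathway = out$pathway, fm = out$fm)
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}
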