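# End-to-end orchestration of the comparative study on synthetic data:
# simulate -> cross-validate factor counts -> fit the four models ->
# evaluate -> figures of merit, with optional CSV/JSON/plot output.

#' Simulate a paired calibration + validation study
#'
#' Generates spectra for the 25-sample training design and the 16-sample
#' validation set under one artifact configuration (the validation set uses
#' a shifted seed so its noise and artifact draws are independent of the
#' training set's).
#'
#' @param artifacts an [artifact_config()].
#' @param S pure-component spectra (default [default_pure_spectra()]).
#' @param design a `calibration_design` (default: the study design).
#' @param validation a `validation_set` (default: the study test set).
#' @return list with `calibration` and `validation` `uv_dataset`s.
#' @export
simulate_study <- function(artifacts = artifact_config(),
                           S = default_pure_spectra(),
                           design = generate_design(),
                           validation = validation_set_table()) {
  art_val <- artifacts
  art_val$seed <- artifacts$seed + 1000L
  list(
    calibration = generate_dataset(design, S, artifacts),
    validation = generate_dataset(validation, S, art_val)
  )
}

#' Run the full comparative study on a simulated dataset
#'
#' Optionally selects per-analyte factor counts by LOO cross-validation,
#' fits CLS and the three augmented models, evaluates recoveries and RMSE on
#' training and validation subsets, and computes figures of merit.
#'
#' @param study output of [simulate_study()] (or a compatible list).
#' @param n_factors named list (`osc`, `dosc`, `nap`) of per-analyte factor
#'   counts; NULL runs [cv_factor_scan()] over `factor_range` for every
#'   analyte and model.
#' @param analytes analyte column indices (default 1:3).
#' @param factor_range factor counts scanned when `n_factors` is NULL.
#' @param rule,level factor-selection rule and level ([select_factors()]).
#' @param noise noise level for the analytical sensitivity.
#' @param out_dir optional directory; when given, per-sample and summary
#'   CSVs, a figures-of-merit CSV, CV CSVs and PRESS profile plots are
#'   written there.
#' @return list with `models`, `report`, `fom`, `cv` (NULL if factor counts
#'   were supplied) and `n_factors`.
#' @export
run_comparison <- function(study, n_factors = NULL, analytes = 1:3,
                           factor_range = 1:10,
                           rule = c("haaland-thomas", "min"), level = 0.25,
                           noise = 0.001, out_dir = NULL) {
  rule <- match.arg(rule)
  A <- study$calibration$spectra
  C <- study$calibration$concentrations
  cv <- NULL
  if (is.null(n_factors)) {
    kinds <- c("osc", "dosc", "nap")
    cv <- list()
    n_factors <- stats::setNames(vector("list", length(kinds)), kinds)
    for (kind in kinds) {
      sel <- integer(length(analytes))
      for (i in seq_along(analytes)) {
        res <- cv_factor_scan(A, C, analytes[i], kind,
                              factors = factor_range, rule = rule,
                              level = level)
        sel[i] <- res$selected
        cv[[paste(kind, res$analyte, sep = "_")]] <- res
      }
      n_factors[[kind]] <- sel
    }
  }
  models <- fit_comparison_models(A, C, n_factors, analytes)
  report <- evaluate_run(models, study$calibration, study$validation,
                         analytes)
  fom <- fom_table(A, C, analytes = analytes,
                   n_factors = list(osc = n_factors$osc,
                                    dosc = NULL, nap = NULL),
                   noise = noise)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_evaluation_report(report,
                            file.path(out_dir, "samples.csv"),
                            file.path(out_dir, "summary.csv"),
                            file.path(out_dir, "report.json"))
    utils::write.csv(fom, file.path(out_dir, "figures_of_merit.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(cv)) {
      write_cv_csv(cv, file.path(out_dir, "cv_press.csv"))
      press_profile_plot(cv, file.path(out_dir, "press_profiles.png"))
    }
  }
  list(models = models, report = report, fom = fom, cv = cv,
       n_factors = n_factors)
}

#' Write a simulated study to CSV files
#'
#' Spectra and concentration CSVs for the calibration and validation sets;
#' the validation concentration file carries the IN/OUT position column.
#' Reruns with the same artifact seed are byte-identical.
#'
#' @param study output of [simulate_study()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_study_csv <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    write_spectra_csv(study$calibration$spectra,
                      file.path(out_dir, "calibration_spectra.csv")),
    write_design_csv(study$calibration$concentrations,
                     file.path(out_dir, "calibration_concentrations.csv")),
    write_spectra_csv(study$validation$spectra,
                      file.path(out_dir, "validation_spectra.csv"))
  )
  vc <- data.frame(study$validation$concentrations,
                   position = study$validation$position,
                   check.names = FALSE)
  utils::write.csv(vc, file.path(out_dir, "validation_concentrations.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(c(paths, file.path(out_dir, "validation_concentrations.csv")))
}
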