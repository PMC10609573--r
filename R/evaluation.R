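# Recovery, RMSEC/RMSEP, subset summaries and the statistical comparison
# against a reference method's summary statistics.

#' Recovery percentage
#'
#' `100 * predicted / taken`; 100 is a perfect prediction.
#'
#' @param taken true concentrations (ug/mL), strictly positive.
#' @param predicted predicted concentrations (ug/mL).
#' @return recovery percentages.
#' @export
recovery_percent <- function(taken, predicted) {
  stopifnot(length(taken) == length(predicted))
  if (any(taken <= 0)) stop("taken concentrations must be positive",
                            call. = FALSE)
  100 * predicted / taken
}

#' Root mean squared error with an explicit divisor
#'
#' `sqrt(sum((taken - predicted)^2) / divisor)`.  The calibration error
#' (RMSEC) of the quinary study divides by the number of training samples
#' (n = 25); the prediction error (RMSEP) divides by the number of evaluated
#' test samples.  An `n - 1` divisor is available for the alternative
#' convention.
#'
#' @param taken,predicted equal-length concentration vectors (ug/mL).
#' @param divisor positive count (default `length(taken)`).
#' @return RMSE in ug/mL.
#' @export
rmse <- function(taken, predicted, divisor = length(taken)) {
  if (length(taken) != length(predicted)) {
    stop("taken and predicted must have equal length", call. = FALSE)
  }
  stopifnot(divisor > 0)
  sqrt(sum((taken - predicted)^2) / divisor)
}

#' Mean and sample standard deviation of recoveries
#'
#' @param recoveries recovery percentages.
#' @return list with `mean`, `sd` (n - 1 divisor) and `n`.
#' @export
summarize_recoveries <- function(recoveries) {
  n <- length(recoveries)
  if (n < 2L) stop("at least two recoveries are needed for an SD",
                   call. = FALSE)
  list(mean = mean(recoveries), sd = stats::sd(recoveries), n = n)
}

#' Pooled two-sample t statistic from summary statistics
#'
#' Equal-variance pooled t, signed as proposed method minus reference:
#' `t = (mean1 - mean2) / SE` with the pooled standard error.
#'
#' @param mean1,sd1,n1 proposed-method mean recovery, SD and replicate count.
#' @param mean2,sd2,n2 reference-method summaries.
#' @return the t statistic (Inf with a warning if the pooled variance is
#'   zero while the means differ; 0 if both are zero).
#' @export
pooled_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    if (mean1 == mean2) return(0)
    warning("zero pooled variance with unequal means", call. = FALSE)
    return(sign(mean1 - mean2) * Inf)
  }
  (mean1 - mean2) / se
}

#' Variance-ratio (F) statistic from two standard deviations
#'
#' The larger variance goes in the numerator, so F >= 1 by construction.
#'
#' @param sd1,sd2 standard deviations, both positive.
#' @return the F statistic.
#' @export
variance_ratio <- function(sd1, sd2) {
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive",
                                 call. = FALSE)
  (max(sd1, sd2) / min(sd1, sd2))^2
}

#' Compare a proposed method against a reference from summary statistics
#'
#' Computes the pooled t (proposed minus reference), the variance-ratio F,
#' and the two-sided t / one-sided F critical values at p = 0.05 (t: 2.228
#' at 10 df; F: 5.050 at 5, 5 df for two six-replicate assays).
#'
#' @inheritParams pooled_t
#' @return list with `t`, `t_crit`, `F`, `F_crit`, `t_significant`,
#'   `F_significant`.
#' @export
compare_methods <- function(mean1, sd1, n1, mean2, sd2, n2) {
  t_stat <- pooled_t(mean1, sd1, n1, mean2, sd2, n2)
  t_crit <- stats::qt(0.975, n1 + n2 - 2)
  f_stat <- variance_ratio(sd1, sd2)
  df <- if (sd1 >= sd2) c(n1 - 1, n2 - 1) else c(n2 - 1, n1 - 1)
  f_crit <- stats::qf(0.95, df[1], df[2])
  list(t = t_stat, t_crit = t_crit, F = f_stat, F_crit = f_crit,
       t_significant = abs(t_stat) > t_crit,
       F_significant = f_stat > f_crit)
}

model_labels <- c(cls = "CLS", osc = "OSC", dosc = "DOSC", nap = "NAP")

#' Fit the full comparison model set
#'
#' One plain CLS model on all components, plus -- per analyte -- one OSC, one
#' DOSC and one NAP augmented model at that analyte's factor count.  OSC and
#' DOSC filters are fitted against the full concentration block; NAP is
#' analyte-specific by construction.
#'
#' @param A,C calibration spectra and concentrations.
#' @param n_factors named list with elements `osc`, `dosc`, `nap`, each a
#'   vector of factor counts indexed by analyte.
#' @param analytes analyte column indices (default 1:3).
#' @return nested list: `$cls` and `$osc`/`$dosc`/`$nap`, the latter lists
#'   indexed by analyte name.
#' @export
fit_comparison_models <- function(A, C, n_factors, analytes = 1:3) {
  C <- as.matrix(C)
  anames <- colnames(C)[analytes]
  models <- list(cls = fit_cls(A, C))
  for (kind in c("osc", "dosc", "nap")) {
    models[[kind]] <- stats::setNames(lapply(seq_along(analytes), function(i) {
      f <- n_factors[[kind]][i]
      fit_augmented(A, C, kind = kind, n_factors = f,
                    analyte = analytes[i])
    }), anames)
  }
  models
}

#' Evaluate the four models on training and validation data
#'
#' Produces the full per-sample and summary report: recovery of every sample
#' for every analyte and model; per-subset (training / validation-IN /
#' validation-OUT) mean and SD of the recoveries; RMSEC over the training
#' set (divisor n); RMSEP over the out-of-space validation samples (divisor
#' n_out) plus a whole-validation-set RMSEP.
#'
#' @param models model set from [fit_comparison_models()].
#' @param cal,val `uv_dataset` objects; `val$position` labels IN/OUT rows.
#' @param analytes analyte column indices.
#' @return object of class `evaluation_report`: list with `samples` (long
#'   data frame) and `summary`.
#' @export
evaluate_run <- function(models, cal, val, analytes = 1:3) {
  anames <- colnames(cal$concentrations)[analytes]
  if (is.null(val$position)) stop("validation set needs IN/OUT labels",
                                  call. = FALSE)
  sets <- list(
    training = list(A = cal$spectra, C = cal$concentrations,
                    subset = rep("training", nrow(cal$spectra))),
    validation = list(A = val$spectra, C = val$concentrations,
                      subset = val$position)
  )
  rows <- list()
  for (set_name in names(sets)) {
    s <- sets[[set_name]]
    for (kind in names(models)) {
      for (i in seq_along(analytes)) {
        a <- analytes[i]
        model <- if (kind == "cls") models$cls else models[[kind]][[i]]
        pred <- predict_analyte(model, s$A, a)
        taken <- s$C[, a]
        rows[[length(rows) + 1L]] <- data.frame(
          set = set_name, subset = s$subset,
          sample = seq_along(taken),
          analyte = anames[i], model = model_labels[[kind]],
          taken = taken, predicted = as.numeric(pred),
          recovery = recovery_percent(taken, as.numeric(pred))
        )
      }
    }
  }
  samples <- do.call(rbind, rows)
  rownames(samples) <- NULL
  summary <- do.call(rbind, lapply(split(
    samples, list(samples$analyte, samples$model, samples$subset),
    drop = TRUE), function(d) {
      if (nrow(d) == 0L) stop("empty subset", call. = FALSE)
      st <- summarize_recoveries(d$recovery)
      data.frame(analyte = d$analyte[1L], model = d$model[1L],
                 subset = d$subset[1L], n = st$n,
                 mean_recovery = st$mean, sd_recovery = st$sd,
                 rmse = rmse(d$taken, d$predicted))
    }))
  # whole-validation-set RMSEP as an auxiliary row
  vd <- samples[samples$set == "validation", ]
  extra <- do.call(rbind, lapply(split(vd, list(vd$analyte, vd$model),
                                       drop = TRUE), function(d) {
    st <- summarize_recoveries(d$recovery)
    data.frame(analyte = d$analyte[1L], model = d$model[1L],
               subset = "validation-all", n = st$n,
               mean_recovery = st$mean, sd_recovery = st$sd,
               rmse = rmse(d$taken, d$predicted))
  }))
  summary <- rbind(summary, extra)
  rownames(summary) <- NULL
  structure(list(samples = samples, summary = summary),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report:", nrow(x$samples), "sample predictions\n")
  print(x$summary, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Write an evaluation report to CSV (and optionally JSON)
#'
#' @param report an `evaluation_report`.
#' @param samples_path,summary_path CSV output files.
#' @param json_path optional path for an unrounded machine-readable copy.
#' @return invisibly, the paths written.
#' @export
write_evaluation_report <- function(report, samples_path, summary_path,
                                    json_path = NULL) {
  utils::write.csv(report$samples, samples_path, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(report$summary, summary_path, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(report), json_path, digits = NA,
                         auto_unbox = TRUE, dataframe = "rows", pretty = TRUE)
  }
  invisible(c(samples_path, summary_path, json_path))
}
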