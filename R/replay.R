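# Replay of the published result tables from their printed inputs: taken
# concentrations and per-sample recovery percentages for the training and
# validation sets, and per-method summary statistics for the dosage-form
# assays.  The replay recomputes every derivable summary (mean, SD, RMSEC,
# RMSEP, pooled t, variance-ratio F) from those inputs.

read_fixture <- function(name) {
  path <- system.file("extdata", name, package = "augcls", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}

#' Published per-sample recoveries (fixtures)
#'
#' Long-format tables of the published per-sample recovery percentages:
#' training set (25 mixtures) and validation set (16 mixtures with IN/OUT
#' position), for each analyte (PYR, CYC, MEC) and model (CLS, OSC, DOSC,
#' NAP).
#'
#' @return data frame with columns `analyte`, `sample`, (`position`,)
#'   `taken`, `CLS`, `OSC`, `DOSC`, `NAP`.
#' @export
training_recoveries_table <- function() read_fixture("training_recoveries.csv")

#' @rdname training_recoveries_table
#' @export
validation_recoveries_table <- function() {
  read_fixture("validation_recoveries.csv")
}

#' Published dosage-form summary statistics (fixture)
#'
#' Mean recovery, SD and replicate count of each chemometric method and of
#' the reference HPLC method on the two marketed tablet formulations,
#' together with the printed t and F statistics.
#'
#' @return data frame with columns `formulation`, `analyte`, `method`,
#'   `mean`, `sd`, `n`, `t_printed`, `f_printed`.
#' @export
dosage_form_summaries <- function() read_fixture("dosage_form_summaries.csv")

#' Replay the training-set summary rows from printed recoveries
#'
#' For every analyte x model block: predicted = taken * recovery / 100, then
#' mean recovery, SD (n - 1) and RMSEC with divisor n = 25.
#'
#' @return data frame: analyte, model, n, mean_recovery, sd_recovery, rmsec.
#' @export
replay_training_table <- function() {
  d <- training_recoveries_table()
  grid <- expand.grid(analyte = unique(d$analyte),
                      model = c("CLS", "OSC", "DOSC", "NAP"),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    b <- d[d$analyte == grid$analyte[i], ]
    pred <- b$taken * b[[grid$model[i]]] / 100
    st <- summarize_recoveries(b[[grid$model[i]]])
    data.frame(analyte = grid$analyte[i], model = grid$model[i], n = st$n,
               mean_recovery = st$mean, sd_recovery = st$sd,
               rmsec = rmse(b$taken, pred, divisor = nrow(b)))
  }))
  rownames(out) <- NULL
  out
}

#' Replay the validation-set summary rows from printed recoveries
#'
#' Per analyte x model: mean and SD of the in-space and out-of-space
#' recoveries, and RMSEP over the eight out-of-space samples (divisor 8).
#'
#' @return data frame: analyte, model, subset, n, mean_recovery,
#'   sd_recovery, rmsep (RMSEP only on the OUT rows).
#' @export
replay_validation_table <- function() {
  d <- validation_recoveries_table()
  grid <- expand.grid(analyte = unique(d$analyte),
                      model = c("CLS", "OSC", "DOSC", "NAP"),
                      position = c("IN", "OUT"),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    b <- d[d$analyte == grid$analyte[i] & d$position == grid$position[i], ]
    r <- b[[grid$model[i]]]
    st <- summarize_recoveries(r)
    rmsep <- if (grid$position[i] == "OUT") {
      rmse(b$taken, b$taken * r / 100, divisor = nrow(b))
    } else NA_real_
    data.frame(analyte = grid$analyte[i], model = grid$model[i],
               subset = grid$position[i], n = st$n,
               mean_recovery = st$mean, sd_recovery = st$sd, rmsep = rmsep)
  }))
  rownames(out) <- NULL
  out
}

#' Replay the dosage-form method comparison from printed summaries
#'
#' Pooled two-sample t (proposed minus reference) and variance-ratio F for
#' every chemometric method against the reference HPLC summaries of the same
#' formulation and analyte, with p = 0.05 critical values.
#'
#' @return data frame with the recomputed `t`, `F`, critical values, and the
#'   printed statistics alongside.
#' @export
replay_method_comparison <- function() {
  d <- dosage_form_summaries()
  ref <- d[d$method == "HPLC", ]
  prop <- d[d$method != "HPLC", ]
  out <- do.call(rbind, lapply(seq_len(nrow(prop)), function(i) {
    p <- prop[i, ]
    r <- ref[ref$formulation == p$formulation & ref$analyte == p$analyte, ]
    cmp <- compare_methods(p$mean, p$sd, p$n, r$mean, r$sd, r$n)
    data.frame(formulation = p$formulation, analyte = p$analyte,
               method = p$method, t = cmp$t, t_crit = cmp$t_crit,
               F = cmp$F, F_crit = cmp$F_crit,
               t_printed = p$t_printed, f_printed = p$f_printed)
  }))
  rownames(out) <- NULL
  out
}

#' Replay all published tables
#'
#' @return list with elements `training`, `validation`, `comparison`.
#' @export
replay_published_tables <- function() {
  list(training = replay_training_table(),
       validation = replay_validation_table(),
       comparison = replay_method_comparison())
}
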