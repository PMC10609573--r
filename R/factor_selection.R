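# Leave-one-out cross-validation over the number of filter factors, PRESS,
# and optimal-factor selection (minimum-PRESS or the Haaland-Thomas F-ratio
# rule).

fit_kind <- function(A, C, kind, n_factors, analyte, ...) {
  switch(kind,
         cls = fit_cls(A, C),
         fit_augmented(A, C, kind = kind, n_factors = n_factors,
                       analyte = analyte, ...))
}

predict_analyte <- function(model, A_new, analyte) {
  Chat <- predict(model, A_new)
  if (inherits(model, "augmented_cls") && model$kind == "nap") {
    Chat[, 1L]
  } else {
    Chat[, analyte]
  }
}

#' Leave-one-out PRESS for one analyte and factor count
#'
#' For each of the N calibration samples the filter (if any) and the CLS
#' model are refitted on the other N - 1 samples and the held-out sample's
#' analyte concentration is predicted; PRESS is the sum of the squared
#' prediction errors over all N holds.
#'
#' @param A,C calibration spectra and concentrations.
#' @param analyte analyte column index or name.
#' @param kind `"cls"` (no filter), `"osc"`, `"dosc"` or `"nap"`.
#' @param n_factors filter factor count (ignored for `"cls"`).
#' @param ... passed to the filter fit.
#' @return PRESS in (ug/mL)^2.
#' @export
loo_press <- function(A, C, analyte, kind = c("cls", "osc", "dosc", "nap"),
                      n_factors = NULL, ...) {
  kind <- match.arg(kind)
  A <- as.matrix(A); C <- as.matrix(C)
  if (is.character(analyte)) analyte <- match(analyte, colnames(C))
  n <- nrow(A)
  err2 <- vapply(seq_len(n), function(i) {
    model <- tryCatch(
      fit_kind(A[-i, , drop = FALSE], C[-i, , drop = FALSE],
               kind, n_factors, analyte, ...),
      error = function(e) {
        stop("LOO fold ", i, " (held-out sample ", i, "): ",
             conditionMessage(e), call. = FALSE)
      })
    pred <- predict_analyte(model, A[i, , drop = FALSE], analyte)
    (pred - C[i, analyte])^2
  }, numeric(1L))
  sum(err2)
}

#' Select the number of factors from a PRESS profile
#'
#' Rule `"min"` takes the factor count with the smallest PRESS (ties break
#' to the smaller count).  Rule `"haaland-thomas"` takes the smallest count
#' whose F-ratio `PRESS / min(PRESS)` is below the critical F value at
#' probability `level` with `n, n` degrees of freedom -- the parsimonious
#' convention of Haaland and Thomas.
#'
#' @param press vector of PRESS values.
#' @param factors factor counts evaluated (default `seq_along(press)`).
#' @param rule `"haaland-thomas"` (default) or `"min"`.
#' @param level probability level of the F test (default 0.25).
#' @param n number of cross-validated samples (default 25, the size of the
#'   quinary training design).
#' @return the selected factor count.
#' @export
select_factors <- function(press, factors = seq_along(press),
                           rule = c("haaland-thomas", "min"),
                           level = 0.25, n = 25L) {
  rule <- match.arg(rule)
  if (length(press) == 0L) stop("no PRESS values supplied", call. = FALSE)
  stopifnot(length(press) == length(factors), all(press > 0))
  if (rule == "min") {
    return(factors[which.min(press)])
  }
  fratio <- press / min(press)
  crit <- stats::qf(1 - level, n, n)
  factors[which(fratio < crit)[1L]]
}

#' Cross-validated PRESS profile and factor selection
#'
#' Runs [loo_press()] for every factor count in `factors` and applies
#' [select_factors()].
#'
#' @inheritParams loo_press
#' @param factors factor counts to evaluate (default 1:10, covering the
#'   optima a well-behaved quinary system needs).
#' @param rule,level selection rule and level, see [select_factors()].
#' @return object of class `cv_result`: list with `analyte`, `kind`,
#'   `profile` (data frame: factors, press, log_press, selected) and
#'   `selected`.
#' @export
cv_factor_scan <- function(A, C, analyte, kind = c("osc", "dosc", "nap"),
                           factors = 1:10, rule = c("haaland-thomas", "min"),
                           level = 0.25, ...) {
  kind <- match.arg(kind)
  rule <- match.arg(rule)
  A <- as.matrix(A); C <- as.matrix(C)
  if (is.character(analyte)) analyte <- match(analyte, colnames(C))
  press <- vapply(factors, function(f) {
    loo_press(A, C, analyte, kind, n_factors = f, ...)
  }, numeric(1L))
  sel <- select_factors(press, factors, rule = rule, level = level,
                        n = nrow(A))
  profile <- data.frame(factors = factors, press = press,
                        log_press = log10(press),
                        selected = factors == sel)
  structure(list(analyte = if (!is.null(colnames(C))) colnames(C)[analyte]
                 else analyte,
                 kind = kind, profile = profile, selected = sel,
                 rule = rule, level = level),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("LOO-CV (", toupper(x$kind), ", analyte ", x$analyte, "): selected ",
      x$selected, " factor(s) by rule '", x$rule, "'\n", sep = "")
  print(x$profile, row.names = FALSE)
  invisible(x)
}

#' Plot log10(PRESS) against the number of factors
#'
#' One panel per `cv_result`, with the selected factor count marked.
#'
#' @param cv a `cv_result` or a list of them.
#' @param path output PNG file.
#' @param width,height device size in pixels.
#' @return `path`, invisibly.
#' @export
press_profile_plot <- function(cv, path, width = 900, height = 700) {
  if (inherits(cv, "cv_result")) cv <- list(cv)
  if (length(cv) == 0L) stop("no CV results to plot", call. = FALSE)
  for (r in cv) {
    if (nrow(r$profile) == 0L) stop("empty factor range", call. = FALSE)
  }
  nr <- floor(sqrt(length(cv)))
  nc <- ceiling(length(cv) / nr)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(nr, nc), mar = c(4, 4, 2, 1))
  for (r in cv) {
    with(r$profile, {
      graphics::plot(factors, log_press, type = "b", pch = 16,
                     xlab = "number of factors",
                     ylab = expression(log[10] ~ PRESS),
                     main = paste0(toupper(r$kind), " / ", r$analyte))
      graphics::points(factors[selected], log_press[selected],
                       col = "red", pch = 8, cex = 1.6)
    })
  }
  invisible(path)
}

#' Write a CV report as CSV
#'
#' Columns: analyte, model, factors, press, log_press, selected.
#'
#' @param cv_list list of `cv_result` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cv_csv <- function(cv_list, path) {
  if (inherits(cv_list, "cv_result")) cv_list <- list(cv_list)
  rows <- do.call(rbind, lapply(cv_list, function(r) {
    cbind(analyte = r$analyte, model = toupper(r$kind), r$profile)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
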