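# Net-analyte-signal figures of merit: sensitivity, analytical sensitivity
# and selectivity, per analyte and per preprocessing model.

#' Net analyte signal of a spectrum against an interferent basis
#'
#' The component of `spectrum` orthogonal to the row span of `interferents`.
#' An empty or NULL basis returns the spectrum itself.
#'
#' @param spectrum numeric vector (a pure-component spectrum or estimate).
#' @param interferents matrix of interferent spectra, one per row (or NULL).
#' @param rtol relative singular-value cutoff defining the numerical span of
#'   the interferent basis.
#' @return the net analyte signal vector.
#' @export
net_analyte_signal <- function(spectrum, interferents = NULL, rtol = 1e-10) {
  s <- as.numeric(spectrum)
  if (is.null(interferents) || length(interferents) == 0L) return(s)
  M <- rbind(interferents)
  sv <- svd(t(M))
  keep <- sv$d > rtol * max(sv$d[1], .Machine$double.eps)
  if (!any(keep)) return(s)
  U <- sv$u[, keep, drop = FALSE]
  as.numeric(s - U %*% crossprod(U, s))
}

#' Figures of merit for one analyte under one preprocessing model
#'
#' The figures are computed in the analyte's own processed space, the frame
#' in which the analyte is actually quantified: OSC and DOSC filters are
#' fitted with the analyte's concentration column as the response (so the
#' removed variation is everything not tied to that analyte), NAP with its
#' interferent-space projector, and `"none"` uses the raw data.  The
#' pure-component profiles of all modelled components are then re-estimated
#' from the filtered data and:
#'
#' * sensitivity `SEN` = norm of the analyte's net analyte signal (its
#'   filtered profile orthogonalised against the other components' filtered
#'   profiles), in AU per ug/mL;
#' * selectivity `SEL` = `SEN` divided by the norm of the analyte's filtered
#'   profile (the fraction of its signal not lost to overlap), in [0, 1];
#' * analytical sensitivity `gamma` = `SEN / noise`, in mL/ug.
#'
#' Interferent profiles weaker than `basis_tol` times the analyte profile
#' are numerically null and excluded from the interferent span.
#'
#' @param A,C calibration spectra and concentrations.
#' @param analyte analyte column index or name.
#' @param filter `"none"`, `"osc"`, `"dosc"` or `"nap"`.
#' @param n_factors filter factor count.  For DOSC and NAP, NULL (default)
#'   uses every achievable factor, removing the whole
#'   concentration-orthogonal (resp. interferent) subspace; for OSC, NULL
#'   defaults to one factor.
#' @param noise instrumental noise level (AU), the denominator of the
#'   analytical sensitivity.
#' @param basis_tol relative threshold for numerically null interferent
#'   profiles (default 1e-6).
#' @return object of class `fom`: list with `analyte`, `model`, `sen`,
#'   `gamma`, `sel`, `noise`, `nas` (the net analyte signal vector).
#' @export
compute_fom <- function(A, C, analyte,
                        filter = c("none", "osc", "dosc", "nap"),
                        n_factors = NULL, noise = 0.001,
                        basis_tol = 1e-6) {
  filter <- match.arg(filter)
  A <- as.matrix(A); C <- as.matrix(C)
  if (noise <= 0) stop("noise must be positive", call. = FALSE)
  if (is.character(analyte)) analyte <- match(analyte, colnames(C))
  ck <- C[, analyte, drop = FALSE]
  if (filter == "none") {
    Af <- A
    Cu <- C
  } else if (filter == "nap") {
    if (is.null(n_factors)) {
      n_factors <- fit_nap(A, C, analyte, 1L)$max_rank
    }
    state <- fit_nap(A, C, analyte, n_factors)
    Af <- state$filtered
    Cu <- C
  } else {
    if (is.null(n_factors)) {
      # DOSC defaults to removing the whole orthogonal subspace; OSC, being
      # iterative and conventionally parsimonious, defaults to one factor
      n_factors <- if (filter == "dosc") fit_dosc(A, ck, 1L)$max_rank else 1L
    }
    state <- switch(filter,
                    osc = fit_osc(A, ck, n_factors),
                    dosc = fit_dosc(A, ck, n_factors))
    Af <- state$filtered
    Cu <- sweep(C, 2L, colMeans(C))
  }
  S_f <- pinv(Cu) %*% Af                 # filtered pure-profile estimates
  s_k <- S_f[analyte, ]
  ns_k <- vnorm(s_k)
  if (ns_k <= basis_tol * max(abs(Af))) {
    stop("undefined figures of merit: the analyte's filtered profile ",
         "is numerically zero", call. = FALSE)
  }
  others <- S_f[-analyte, , drop = FALSE]
  strong <- apply(others, 1L, vnorm) > basis_tol * ns_k
  nas <- net_analyte_signal(s_k, others[strong, , drop = FALSE])
  sen <- vnorm(nas)
  structure(list(analyte = if (!is.null(colnames(C))) colnames(C)[analyte]
                 else analyte,
                 model = filter, n_factors = n_factors,
                 sen = sen, gamma = sen / noise, sel = sen / ns_k,
                 noise = noise, nas = nas),
            class = "fom")
}

#' @export
print.fom <- function(x, ...) {
  cat(sprintf("FOM (%s, %s): SEN %.4g AU.mL/ug, gamma %.4g mL/ug, SEL %.4g\n",
              x$analyte, toupper(x$model), x$sen, x$gamma, x$sel))
  invisible(x)
}

#' Figures-of-merit table over analytes and models
#'
#' @inheritParams compute_fom
#' @param analytes analyte column indices (default 1:3).
#' @param filters preprocessing models to tabulate.
#' @param n_factors optional named list (`osc`, `dosc`, `nap`) of per-analyte
#'   factor counts; NULL entries default as in [compute_fom()].
#' @return data frame with one row per analyte x model.
#' @export
fom_table <- function(A, C, analytes = 1:3,
                      filters = c("osc", "dosc", "nap"),
                      n_factors = NULL, noise = 0.001) {
  rows <- list()
  for (a in analytes) {
    for (f in filters) {
      nf <- if (!is.null(n_factors) && !is.null(n_factors[[f]])) {
        n_factors[[f]][match(a, analytes)]
      }
      fom <- compute_fom(A, C, a, filter = f, n_factors = nf, noise = noise)
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = fom$analyte, model = toupper(f),
        sensitivity = fom$sen, analytical_sensitivity = fom$gamma,
        selectivity = fom$sel)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
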