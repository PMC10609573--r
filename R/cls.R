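# Classical least squares (CLS) calibration: A = C %*% S.  Fitting estimates
# the pure-component spectra S from known concentrations; prediction solves
# each new spectrum for its concentrations against the estimated S.

#' Fit a classical least squares calibration model
#'
#' Solves `A ~ C %*% S` for the pure-component spectra `S` by least squares
#' (rank-revealing SVD pseudoinverse with relative cutoff `rtol`).  All
#' components present in the mixtures -- analytes and impurities alike --
#' must be in `C`.
#'
#' @param A samples x points absorbance matrix.
#' @param C samples x components concentration matrix, full column rank,
#'   with at least as many samples as components.
#' @param rtol relative singular-value cutoff (default 1e-10).
#' @return object of class `cls_model`: list with `S_hat` (components x
#'   points estimated pure spectra), `components`, `grid`, `residual_norm`
#'   and `rtol`.
#' @export
fit_cls <- function(A, C, rtol = 1e-10) {
  A <- as.matrix(A)
  C <- as.matrix(C)
  if (nrow(A) != nrow(C)) stop("A and C must have aligned rows", call. = FALSE)
  if (nrow(C) < ncol(C)) {
    stop("calibration needs at least as many samples as components",
         call. = FALSE)
  }
  r <- numerical_rank(C, rtol)
  if (r < ncol(C)) {
    qrC <- qr(C, LAPACK = TRUE)
    bad <- qrC$pivot[(r + 1L):ncol(C)]
    nm <- if (is.null(colnames(C))) paste0("column ", bad) else colnames(C)[bad]
    stop("calibration error: concentration matrix is rank deficient; ",
         "collinear component(s): ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  S_hat <- pinv(C, rtol) %*% A
  rownames(S_hat) <- colnames(C)
  structure(
    list(S_hat = S_hat,
         components = colnames(C),
         grid = attr(A, "grid"),
         residual_norm = sqrt(frob2(A - C %*% S_hat)),
         rtol = rtol),
    class = "cls_model"
  )
}

#' Predict concentrations from new spectra with a CLS model
#'
#' Each spectrum is solved by least squares against the estimated pure
#' spectra; negative estimates are returned as-is (the model is
#' unconstrained).
#'
#' @param object a [fit_cls()] model.
#' @param newdata samples x points absorbance matrix on the model's grid.
#' @param ... unused.
#' @return samples x components matrix of predicted concentrations (ug/mL).
#' @export
predict.cls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  g <- attr(newdata, "grid")
  if (!is.null(g) && !is.null(object$grid) && !same_grid(g, object$grid)) {
    stop("wavelength grid of new spectra does not match the model",
         call. = FALSE)
  }
  if (ncol(newdata) != ncol(object$S_hat)) {
    stop("new spectra have ", ncol(newdata), " points; model expects ",
         ncol(object$S_hat), call. = FALSE)
  }
  Chat <- newdata %*% t(pinv(t(object$S_hat), object$rtol))
  colnames(Chat) <- object$components
  rownames(Chat) <- rownames(newdata)
  Chat
}

#' @export
print.cls_model <- function(x, ...) {
  cat("CLS model:", nrow(x$S_hat), "components x", ncol(x$S_hat),
      "wavelengths\n")
  cat("  components:", paste(x$components, collapse = ", "), "\n")
  cat("  residual norm:", format(x$residual_norm, digits = 4), "\n")
  invisible(x)
}

#' Serialize / restore a CLS model as a human-readable JSON file
#'
#' @param model a `cls_model`.
#' @param path file path.
#' @return `path` invisibly (write); the restored model (read).
#' @export
write_cls_model <- function(model, path) {
  obj <- list(
    components = model$components,
    grid = if (is.null(model$grid)) NULL else
      model$grid[c("start", "stop", "step")],
    S_hat = model$S_hat,
    residual_norm = model$residual_norm,
    rtol = model$rtol
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cls_model
#' @export
read_cls_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  S_hat <- as.matrix(obj$S_hat)
  rownames(S_hat) <- obj$components
  grid <- if (!is.null(obj$grid)) {
    wavelength_grid(obj$grid$start, obj$grid$stop, obj$grid$step)
  }
  if (!is.null(grid) && length(grid$nm) == ncol(S_hat)) {
    colnames(S_hat) <- as.character(grid$nm)
  }
  structure(
    list(S_hat = S_hat, components = obj$components, grid = grid,
         residual_norm = obj$residual_norm, rtol = obj$rtol),
    class = "cls_model"
  )
}
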