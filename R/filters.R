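# Concentration-orthogonal spectral filters: OSC (iterative), DOSC (direct)
# and NAP (net analyte preprocessing).  Each fit returns a filter state that
# can be re-applied to new spectra; quantitation then proceeds by CLS on the
# filtered spectra (see fit_augmented()).
#
# Conventions: OSC and DOSC mean-centre both the spectra and the
# concentration block internally; the centring vectors are stored in the
# state and reused at application time, so filtered output lives in the
# centred space and the downstream regression works against centred
# concentrations.  NAP deflates with the uncentred analyte column and its
# projector applies to raw spectra (its stored centring vector is zero).

new_filter_state <- function(kind, n_factors, x_center, c_center, extras,
                             filtered) {
  structure(
    c(list(kind = kind, n_factors = n_factors, x_center = x_center,
           c_center = c_center, filtered = filtered), extras),
    class = c(paste0(kind, "_filter"), "filter_state")
  )
}

#' Fit an orthogonal signal correction (OSC) filter
#'
#' Iteratively extracts `n_factors` spectral factors of maximal variance
#' constrained to be orthogonal to every column of `C`, and deflates them
#' from the data.  Per factor: start from the dominant principal-component
#' score of the (current, centred) data, then alternate (i) orthogonalising
#' the score against all concentration columns and (ii) regressing it back
#' onto the data, until the score stabilises; finally deflate by the
#' score-loading product.  Weights are stored so the same correction applies
#' to new spectra.
#'
#' @param A samples x points absorbance matrix.
#' @param C samples x components concentration matrix (row-aligned with `A`).
#'   Quantitation models use all modelled components; analyte-specific
#'   figures of merit pass a single column.
#' @param n_factors number of factors to remove (0 gives a degenerate state
#'   that only centres).
#' @param tol relative convergence tolerance on the score (default 1e-10).
#' @param max_iter iteration cap per factor; non-convergence is recorded in
#'   the state as a warning flag, not an error.
#' @param rtol pseudoinverse cutoff.
#' @return a `filter_state` of kind `"osc"` with per-factor weight and
#'   loading vectors, calibration scores, and the filtered (centred,
#'   deflated) calibration matrix.
#' @export
fit_osc <- function(A, C, n_factors = 1L, tol = 1e-10, max_iter = 500L,
                    rtol = 1e-10) {
  A <- as.matrix(A); C <- as.matrix(C)
  stopifnot(nrow(A) == nrow(C), n_factors >= 0L)
  if (n_factors >= min(nrow(A) - 1L, ncol(A))) {
    stop("n_factors must be below min(samples - 1, points)", call. = FALSE)
  }
  x_center <- colMeans(A)
  c_center <- colMeans(C)
  X <- sweep(A, 2L, x_center)
  Y <- sweep(C, 2L, c_center)
  Ypinv <- pinv(Y, rtol)
  p <- ncol(X)
  W <- matrix(0, p, n_factors)
  P <- matrix(0, p, n_factors)
  Tsc <- matrix(0, nrow(X), n_factors)
  converged <- logical(n_factors)
  for (f in seq_len(n_factors)) {
    sv <- svd(X, nu = 1L, nv = 0L)
    t_score <- sv$u[, 1L] * sv$d[1L]
    Xp <- pinv(X, rtol)
    scale0 <- sqrt(frob2(X))
    w <- NULL
    for (it in seq_len(max_iter)) {
      t_orth <- t_score - Y %*% (Ypinv %*% t_score)
      if (vnorm(t_orth) <= rtol * scale0) {
        # no concentration-orthogonal variation left: null factor
        converged[f] <- TRUE
        t_score <- t_orth
        break
      }
      w <- Xp %*% t_orth
      nw <- vnorm(w)
      if (nw == 0) break
      w <- w / nw
      t_new <- X %*% w
      delta <- vnorm(t_new - t_score)
      t_score <- t_new
      if (delta <= tol * max(vnorm(t_score), .Machine$double.eps)) {
        converged[f] <- TRUE
        break
      }
    }
    # enforce exact orthogonality of the stored score to the
    # concentration block, then take the loading from the current data
    t_score <- t_score - Y %*% (Ypinv %*% t_score)
    nt2 <- sum(t_score^2)
    if (nt2 <= rtol^2 * frob2(X)) {
      # no orthogonal variation left; keep a null factor
      if (!is.null(w)) W[, f] <- w
      next
    }
    loading <- crossprod(X, t_score) / nt2
    X <- X - tcrossprod(t_score, loading)
    W[, f] <- w
    P[, f] <- loading
    Tsc[, f] <- t_score
  }
  if (n_factors > 0L && !all(converged)) {
    warning("OSC factor(s) ", paste(which(!converged), collapse = ", "),
            " did not converge in ", max_iter, " iterations", call. = FALSE)
  }
  new_filter_state("osc", n_factors, x_center, c_center,
                   list(weights = W, loadings = P, scores = Tsc,
                        converged = converged, tol = tol,
                        max_iter = max_iter),
                   filtered = X)
}

#' Fit a direct orthogonal signal correction (DOSC) filter
#'
#' Non-iterative construction: the concentration block is projected onto the
#' row space of the centred data; the part of the data orthogonal to that
#' projection is formed, its first `n_factors` principal components are
#' taken, and their scores are re-expressed through the data's pseudoinverse
#' so the correction applies to new samples.
#'
#' @inheritParams fit_osc
#' @param rank_tol relative tolerance defining the numerical rank of the
#'   concentration-orthogonal part.
#' @return a `filter_state` of kind `"dosc"` with projection weight and
#'   loading pairs, calibration scores, and the filtered calibration matrix.
#' @export
fit_dosc <- function(A, C, n_factors = 1L, rank_tol = 1e-10) {
  A <- as.matrix(A); C <- as.matrix(C)
  stopifnot(nrow(A) == nrow(C), n_factors >= 1L)
  x_center <- colMeans(A)
  c_center <- colMeans(C)
  X <- sweep(A, 2L, x_center)
  Y <- sweep(C, 2L, c_center)
  Xpinv <- pinv(X, rank_tol)
  Yhat <- X %*% (Xpinv %*% Y)            # Y projected onto range(X)
  X_orth <- X - Yhat %*% (pinv(Yhat, rank_tol) %*% X)
  sv <- svd(X_orth)
  # rank of the orthogonal part relative to the scale of the data itself,
  # so a numerically null orthogonal part has rank 0
  d_ref <- svd(X, nu = 0L, nv = 0L)$d[1L]
  r <- sum(sv$d > rank_tol * max(d_ref, .Machine$double.eps))
  if (n_factors > r) {
    stop("DOSC: requested ", n_factors, " factors but the ",
         "concentration-orthogonal part has numerical rank ", r,
         "; at most ", r, " factor(s) are achievable", call. = FALSE)
  }
  Tsc <- sv$u[, seq_len(n_factors), drop = FALSE] *
    rep(sv$d[seq_len(n_factors)], each = nrow(X))
  # loadings regress the full data on the scores, so deflation removes all
  # data variation along the score directions
  loadings <- crossprod(X, Tsc) %*% solve(crossprod(Tsc))
  weights <- Xpinv %*% Tsc               # new scores: X_new %*% weights
  X_f <- X - tcrossprod(Tsc, loadings)
  new_filter_state("dosc", as.integer(n_factors), x_center, c_center,
                   list(weights = weights, loadings = loadings, scores = Tsc,
                        rank_tol = rank_tol, max_rank = r),
                   filtered = X_f)
}

#' Fit a net analyte preprocessing (NAP) filter for one analyte
#'
#' Deflates the analyte's contribution from the calibration spectra using
#' its (uncentred) concentration column, takes the first `n_factors`
#' principal directions of the remainder as the interferent space, and
#' stores the orthogonal-complement projector.  Applying the projector to
#' any spectrum yields that spectrum's net analyte signal part.
#'
#' @inheritParams fit_osc
#' @param analyte column index or name in `C` of the analyte of interest.
#' @param n_factors dimension of the interferent space to project out; at
#'   most the numerical rank of the analyte-deflated data (with the clean
#'   quinary design this is 4 plus the rank of any planted artifact).
#' @param rank_tol relative rank tolerance.
#' @return a `filter_state` of kind `"nap"` whose `operator` is the
#'   symmetric idempotent projector onto the net-analyte subspace.
#' @export
fit_nap <- function(A, C, analyte, n_factors, rank_tol = 1e-10) {
  A <- as.matrix(A); C <- as.matrix(C)
  stopifnot(nrow(A) == nrow(C), n_factors >= 1L)
  if (is.character(analyte)) analyte <- match(analyte, colnames(C))
  stopifnot(!is.na(analyte), analyte >= 1L, analyte <= ncol(C))
  ck <- cbind(C[, analyte])
  Xk <- A - ck %*% (crossprod(ck, A) / sum(ck^2))  # remove analyte part
  sv <- svd(Xk)
  d_ref <- svd(A, nu = 0L, nv = 0L)$d[1L]
  r <- sum(sv$d > rank_tol * max(d_ref, .Machine$double.eps))
  if (n_factors > r) {
    stop("NAP: requested ", n_factors, " factors but the interferent ",
         "subspace has numerical rank ", r, "; at most ", r,
         " factor(s) are achievable", call. = FALSE)
  }
  V <- sv$v[, seq_len(n_factors), drop = FALSE]
  operator <- diag(ncol(A)) - tcrossprod(V)
  new_filter_state("nap", as.integer(n_factors),
                   x_center = rep(0, ncol(A)),
                   c_center = rep(0, ncol(C)),
                   list(operator = operator, interferent_basis = V,
                        analyte = analyte, rank_tol = rank_tol,
                        max_rank = r),
                   filtered = A %*% operator)
}

#' Apply a fitted filter to new spectra
#'
#' Centres with the stored calibration centring vector, then applies the
#' stored operators in fit order.  Deterministic; the output lives in the
#' filter's working space (centred for OSC/DOSC, raw for NAP).
#'
#' @param state a `filter_state` from [fit_osc()], [fit_dosc()] or
#'   [fit_nap()].
#' @param A samples x points absorbance matrix on the calibration grid.
#' @return the filtered absorbance matrix.
#' @export
apply_filter <- function(state, A) {
  A <- as.matrix(A)
  if (ncol(A) != length(state$x_center)) {
    stop("spectra have ", ncol(A), " points; filter expects ",
         length(state$x_center), call. = FALSE)
  }
  X <- sweep(A, 2L, state$x_center)
  switch(state$kind,
    osc = {
      if (state$n_factors > 0L) {
        for (f in seq_len(state$n_factors)) {
          t_new <- X %*% state$weights[, f, drop = FALSE]
          X <- X - t_new %*% t(state$loadings[, f, drop = FALSE])
        }
      }
      X
    },
    dosc = {
      Tn <- X %*% state$weights
      X - tcrossprod(Tn, state$loadings)
    },
    nap = X %*% state$operator,
    stop("unknown filter kind: ", state$kind, call. = FALSE)
  )
}

#' @export
print.filter_state <- function(x, ...) {
  cat(toupper(x$kind), "filter:", x$n_factors, "factor(s),",
      length(x$x_center), "wavelengths\n")
  invisible(x)
}

#' Fit an augmented CLS model (filter + CLS)
#'
#' For OSC and DOSC the filter is fitted against all columns of `C` and the
#' downstream CLS regresses the filtered (centred) spectra on the centred
#' concentrations of all components; predictions add the calibration
#' concentration means back.  For NAP the filter is analyte-specific and the
#' downstream regression is against that analyte's (uncentred) concentration
#' column alone.
#'
#' @param A,C calibration spectra and concentrations.
#' @param kind `"osc"`, `"dosc"` or `"nap"`.
#' @param n_factors filter factor count (e.g. selected by
#'   [cv_factor_scan()]).
#' @param analyte analyte column (required for NAP).
#' @param ... passed to the filter fit.
#' @return object of class `augmented_cls` with elements `kind`, `filter`,
#'   `cls`, `analyte`.
#' @export
fit_augmented <- function(A, C, kind = c("osc", "dosc", "nap"), n_factors,
                          analyte = NULL, ...) {
  kind <- match.arg(kind)
  C <- as.matrix(C)
  if (kind == "nap") {
    if (is.null(analyte)) stop("NAP requires an analyte", call. = FALSE)
    filter <- fit_nap(A, C, analyte, n_factors, ...)
    ck <- C[, filter$analyte, drop = FALSE]
    cls <- fit_cls(filter$filtered, ck)
    analyte <- filter$analyte
  } else {
    filter <- switch(kind,
                     osc = fit_osc(A, C, n_factors, ...),
                     dosc = fit_dosc(A, C, n_factors, ...))
    Yc <- sweep(C, 2L, filter$c_center)
    cls <- fit_cls(filter$filtered, Yc)
  }
  structure(list(kind = kind, filter = filter, cls = cls, analyte = analyte),
            class = "augmented_cls")
}

#' Predict concentrations with an augmented CLS model
#'
#' @param object a [fit_augmented()] model.
#' @param newdata samples x points absorbance matrix.
#' @param ... unused.
#' @return predicted concentrations: all components (OSC/DOSC) or the single
#'   analyte column (NAP).
#' @export
predict.augmented_cls <- function(object, newdata, ...) {
  Xf <- apply_filter(object$filter, as.matrix(newdata))
  Chat <- predict(object$cls, Xf)
  if (object$kind != "nap") {
    Chat <- sweep(Chat, 2L, object$filter$c_center, "+")
  }
  rownames(Chat) <- rownames(newdata)
  Chat
}

#' @export
print.augmented_cls <- function(x, ...) {
  cat("Augmented CLS (", toupper(x$kind), "), ", x$filter$n_factors,
      " filter factor(s)\n", sep = "")
  invisible(x)
}
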