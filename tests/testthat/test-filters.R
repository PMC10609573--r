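orthogonality <- function(scores, C) {
  Yc <- sweep(C, 2L, colMeans(C))
  max(abs(crossprod(Yc, scores)))
}

test_that("OSC scores are orthogonal to all concentration columns", {
  ds <- artifact_quinary(rank = 2L)
  st <- fit_osc(ds$spectra, ds$concentrations, n_factors = 2L)
  expect_true(all(st$converged))
  expect_lt(orthogonality(st$scores, ds$concentrations),
            1e-8 * sqrt(frob2(st$scores)))
  # removed variation is concentration-orthogonal: CLS on the filtered data
  # still recovers concentrations
  Yc <- sweep(ds$concentrations, 2L, colMeans(ds$concentrations))
  m <- fit_cls(st$filtered, Yc)
  expect_lt(m$residual_norm / sqrt(frob2(ds$spectra)), 1e-6)
})

test_that("OSC removes the concentration-orthogonal part of a planted artifact", {
  ds <- artifact_quinary(rank = 1L)
  clean <- clean_quinary()
  planted2 <- frob2(ds$spectra - clean$spectra)
  st <- fit_osc(ds$spectra, ds$concentrations, n_factors = 1L)
  Xc_clean <- sweep(clean$spectra, 2L, colMeans(clean$spectra))
  # what survives of the artifact is exactly its component along the
  # concentration block: the residual against the clean data has no
  # concentration-orthogonal part left
  R <- st$filtered - Xc_clean
  Yc <- sweep(ds$concentrations, 2L, colMeans(ds$concentrations))
  R_perp <- R - Yc %*% (MASS::ginv(Yc) %*% R)
  expect_lt(frob2(R_perp), 1e-10 * planted2)
  # and the filter did remove most of the planted energy
  expect_lt(frob2(R), planted2)
})

test_that("OSC application to calibration data reproduces the stored filtrate", {
  ds <- artifact_quinary(rank = 2L, noise_sd = 1e-4)
  st <- fit_osc(ds$spectra, ds$concentrations, n_factors = 2L)
  re <- apply_filter(st, ds$spectra)
  expect_equal(re, st$filtered, tolerance = 1e-8)
  expect_error(apply_filter(st, ds$spectra[, 1:10]), "points")
})

test_that("OSC handles degenerate requests", {
  ds <- clean_quinary()
  st0 <- fit_osc(ds$spectra, ds$concentrations, n_factors = 0L)
  expect_equal(st0$filtered,
               sweep(ds$spectra, 2L, colMeans(ds$spectra)),
               ignore_attr = TRUE)
  expect_error(fit_osc(ds$spectra, ds$concentrations, n_factors = 30L),
               "n_factors")
  # noiseless data has no concentration-orthogonal variation: the factor is
  # null and the data passes through unchanged (no spurious warning)
  expect_no_warning(st <- fit_osc(ds$spectra, ds$concentrations, 1L))
  expect_lt(sqrt(frob2(st$filtered - sweep(ds$spectra, 2L,
                                           colMeans(ds$spectra)))),
            1e-8 * sqrt(frob2(ds$spectra)))
})

test_that("DOSC filtrate is orthogonal to the projected concentrations", {
  ds <- artifact_quinary(rank = 2L)
  st <- fit_dosc(ds$spectra, ds$concentrations, n_factors = 2L)
  expect_identical(st$max_rank, 2L)
  X <- sweep(ds$spectra, 2L, colMeans(ds$spectra))
  Y <- sweep(ds$concentrations, 2L, colMeans(ds$concentrations))
  Yhat <- X %*% (MASS::ginv(X) %*% Y)
  expect_lt(max(abs(crossprod(Yhat, st$scores))),
            1e-8 * sqrt(frob2(X)) * sqrt(frob2(Yhat)))
  # removing both factors eliminates the artifact's
  # concentration-orthogonal part; what remains of it lies along Y
  clean <- clean_quinary()
  Xc_clean <- sweep(clean$spectra, 2L, colMeans(clean$spectra))
  R <- st$filtered - Xc_clean
  R_perp <- R - Y %*% (MASS::ginv(Y) %*% R)
  expect_lt(frob2(R_perp), 1e-12 * frob2(X))
})

test_that("DOSC errors when more factors are requested than achievable", {
  ds <- artifact_quinary(rank = 2L)
  expect_error(fit_dosc(ds$spectra, ds$concentrations, n_factors = 3L),
               "at most 2 factor")
  clean <- clean_quinary()
  expect_error(fit_dosc(clean$spectra, clean$concentrations, n_factors = 1L),
               "rank 0")
})

test_that("DOSC application matches the fitted filtrate and transfers", {
  ds <- artifact_study(rank = 2L, noise_sd = 1e-4)
  st <- fit_dosc(ds$calibration$spectra, ds$calibration$concentrations, 2L)
  re <- apply_filter(st, ds$calibration$spectra)
  expect_equal(re, st$filtered, tolerance = 1e-8)
  # new samples sharing the artifact structure are also cleaned: the
  # filtered validation spectra are fit by the centred concentrations alone
  Xv <- apply_filter(st, ds$validation$spectra)
  Yv <- sweep(ds$validation$concentrations, 2L, st$c_center)
  res <- Xv - Yv %*% (MASS::ginv(Yv) %*% Xv)
  expect_lt(sqrt(frob2(res)), 1e-2 * sqrt(frob2(ds$validation$spectra)))
})

test_that("NAP projector is idempotent and annihilates the interferent space", {
  ds <- artifact_quinary(rank = 2L)
  st <- fit_nap(ds$spectra, ds$concentrations, analyte = "PYR",
                n_factors = 6L)
  P <- st$operator
  expect_equal(P %*% P, P, tolerance = 1e-10)
  expect_equal(t(P), P, tolerance = 1e-12)
  expect_lt(max(abs(P %*% st$interferent_basis)), 1e-10)
  # independent oracle: the projector complement built by qr on the basis
  V <- st$interferent_basis
  Q <- qr.Q(qr(V))
  expect_equal(P, diag(nrow(P)) - tcrossprod(Q), tolerance = 1e-9)
})

test_that("NAP filtering leaves a rank-one analyte contribution", {
  ds <- artifact_quinary(rank = 2L)
  # interferent space: 4 other components + 2 artifact shapes
  st <- fit_nap(ds$spectra, ds$concentrations, analyte = "PYR",
                n_factors = 6L)
  Af <- st$filtered
  sv <- svd(Af)$d
  expect_identical(sum(sv > 1e-8 * sv[1]), 1L)
  # the surviving direction carries the analyte concentrations
  ck <- ds$concentrations[, "PYR"]
  m <- fit_cls(Af, cbind(PYR = ck))
  expect_lt(m$residual_norm, 1e-8 * sqrt(frob2(ds$spectra)))
  expect_error(fit_nap(ds$spectra, ds$concentrations, "PYR", 20L),
               "at most")
})

test_that("augmented models recover known concentrations under artifacts", {
  ds <- artifact_study(rank = 2L)
  cal <- ds$calibration; val <- ds$validation
  for (kind in c("osc", "dosc")) {
    m <- fit_augmented(cal$spectra, cal$concentrations, kind, n_factors = 2L)
    Chat <- predict(m, val$spectra)
    expect_equal(unname(Chat), unname(val$concentrations),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  m <- fit_augmented(cal$spectra, cal$concentrations, "nap",
                     n_factors = 6L, analyte = "CYC")
  pred <- predict(m, val$spectra)[, 1]
  expect_equal(unname(pred), unname(val$concentrations[, "CYC"]),
               tolerance = 1e-6)
  expect_error(fit_augmented(cal$spectra, cal$concentrations, "nap", 6L),
               "analyte")
  expect_output(print(m), "NAP")
})

test_that("plain CLS is biased by the artifact that the filters remove", {
  ds <- artifact_study(rank = 2L, scale = 0.2)
  cal <- ds$calibration; val <- ds$validation
  cls <- fit_cls(cal$spectra, cal$concentrations)
  dosc <- fit_augmented(cal$spectra, cal$concentrations, "dosc", 2L)
  err <- function(Chat) sqrt(mean((Chat[, 1:3] -
                                     val$concentrations[, 1:3])^2))
  expect_gt(err(predict(cls, val$spectra)),
            10 * err(predict(dosc, val$spectra)))
})
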