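test_that("the default wavelength grid covers 221-370 nm at 1 nm", {
  g <- wavelength_grid()
  expect_equal(c(g$start, g$stop, g$step), c(221, 370, 1))
  expect_identical(g$points, 150L)
  expect_error(wavelength_grid(221, 370, 7), "divide the range")
  expect_error(wavelength_grid(370, 221), "start < stop")
})

test_that("pure spectra peak at the declared wavelengths and span rank 5", {
  g <- wavelength_grid()
  S <- quinary_spectra()
  nm <- g$nm
  # absorption maxima at the nominal wavelengths, within one grid step
  # (overlapping secondary bands shift the composite argmax by <= 1 nm)
  expect_lte(abs(nm[which.max(S["PYR", ])] - 290), g$step)
  expect_lte(abs(nm[which.max(S["CYC", ])] - 225), g$step)
  expect_lte(abs(nm[which.max(S["MEC", ])] - 230), g$step)
  expect_true(all(S >= 0))
  # impurities overlap the analytes over 221-300 nm
  idx <- nm >= 221 & nm <= 300
  expect_true(all(S["BEH", idx] > 0))
  expect_true(all(S["BEP", idx] > 0))
  # independent decomposition oracle for the rank
  expect_identical(qr(t(S))$rank, 5L)
  expect_error(default_pure_spectra(wavelength_grid(221, 260, 1)),
               "grid too narrow")
})

test_that("band amplitudes scale the sampled spectrum linearly", {
  bands <- pure_band_params()
  doubled <- bands
  for (i in seq_along(doubled)) doubled[[i]]$amplitude <-
      2 * doubled[[i]]$amplitude
  S1 <- default_pure_spectra(bands = bands)
  S2 <- default_pure_spectra(bands = doubled)
  expect_equal(S2, 2 * S1, ignore_attr = TRUE)
})

test_that("noiseless mixing is exactly Beer-Lambert", {
  S <- quinary_spectra()
  C0 <- matrix(0, 2, 5, dimnames = list(NULL, rownames(S)))
  expect_true(all(mix_spectra(C0, S) == 0))

  # unit concentration of a single component returns its pure spectrum
  C1 <- matrix(0, 1, 5, dimnames = list(NULL, rownames(S)))
  C1[1, "CYC"] <- 1
  expect_equal(as.numeric(mix_spectra(C1, S)), unname(S["CYC", ]))

  # additivity: spectra of c1 and c2 sum to the spectrum of c1 + c2
  set.seed(11)
  c1 <- matrix(runif(5, 1, 10), 1)
  c2 <- matrix(runif(5, 1, 10), 1)
  colnames(c1) <- colnames(c2) <- rownames(S)
  A1 <- mix_spectra(c1, S); A2 <- mix_spectra(c2, S)
  A12 <- mix_spectra(c1 + c2, S)
  expect_equal(unname(A1 + A2), unname(A12))

  expect_error(mix_spectra(-c1, S), "negative")
  bad <- c1; colnames(bad) <- rev(colnames(c1))
  expect_error(mix_spectra(bad, S), "component order")
})

test_that("dataset generation is bit-identical under a fixed seed", {
  art <- artifact_config(noise_sd = 0.001, baseline_rank = 1,
                         baseline_scale = 0.02, scatter_sd = 0.005,
                         seed = 123)
  d1 <- generate_dataset(generate_design(), quinary_spectra(), art)
  d2 <- generate_dataset(generate_design(), quinary_spectra(), art)
  expect_identical(d1$spectra, d2$spectra)
  d3 <- generate_dataset(generate_design(), quinary_spectra(),
                         artifact_config(noise_sd = 0.001,
                                         baseline_rank = 1,
                                         baseline_scale = 0.02,
                                         scatter_sd = 0.005, seed = 124))
  expect_false(identical(d1$spectra, d3$spectra))
})

test_that("noiseless data has rank 5, plus the planted artifact rank", {
  ds <- clean_quinary()
  sv <- svd(ds$spectra)$d
  expect_identical(sum(sv > 1e-10 * sv[1]), 5L)
  da <- artifact_quinary(rank = 2L)
  sva <- svd(da$spectra)$d
  expect_identical(sum(sva > 1e-10 * sva[1]), 7L)
})

test_that("additive noise is zero-mean around the noiseless spectra", {
  S <- quinary_spectra()
  C <- generate_design()$concentrations
  A0 <- mix_spectra(C, S)
  devs <- vapply(1:40, function(s) {
    A <- mix_spectra(C, S, artifact_config(noise_sd = 0.001, seed = s))
    mean(A - A0)
  }, numeric(1))
  # mean over 40 x 3750 iid N(0, 0.001) draws; 4 standard errors
  expect_lt(abs(mean(devs)), 4 * 0.001 / sqrt(40 * length(A0)))
})

test_that("spectra CSV round-trips with its grid", {
  ds <- artifact_quinary(noise_sd = 0.001)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(ds$spectra, path)
  back <- read_spectra_csv(path)
  expect_equal(unname(back), unname(ds$spectra), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(back, "grid")$nm, attr(ds$spectra, "grid")$nm)
})
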