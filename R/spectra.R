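# Synthetic UV spectra: Gaussian-band pure-component absorptivities on a
# 221-370 nm grid and a Beer-Lambert mixing model with optional instrumental
# artifacts (additive noise, polynomial baseline drift, multiplicative
# scatter, an unmodelled interferent).

#' Wavelength grid
#'
#' @param start,stop grid limits in nm (default 221-370 nm, the range over
#'   which the mixture absorbs and solvent/excipient interference is absent).
#' @param step sampling interval in nm (default 1 nm, a standard UV export
#'   interval).
#' @return object of class `wavelength_grid` with fields `start`, `stop`,
#'   `step`, `nm` (the sampled wavelengths) and `points`.
#' @export
wavelength_grid <- function(start = 221, stop = 370, step = 1) {
  stopifnot(start < stop, step > 0)
  n <- (stop - start) / step
  if (abs(n - round(n)) > 1e-8) {
    stop("grid step must divide the range exactly", call. = FALSE)
  }
  nm <- seq(start, stop, by = step)
  structure(list(start = start, stop = stop, step = step,
                 nm = nm, points = length(nm)),
            class = "wavelength_grid")
}

same_grid <- function(g1, g2) {
  isTRUE(all.equal(g1$nm, g2$nm))
}

# Gaussian band: amplitude * exp(-(nm - center)^2 / (2 * width^2))
gaussian_band <- function(nm, center, width, amplitude) {
  amplitude * exp(-((nm - center)^2) / (2 * width^2))
}

#' Band parameters of the default pure-component spectra
#'
#' Each component is a sum of two or three Gaussian bands.  Band centres put
#' the absorption maxima at 290 nm (PYR), 225 nm (CYC) and 230 nm (MEC);
#' the impurity bands (BEH, BEP) overlap all three analytes over
#' 221-300 nm.  Amplitudes are molar-like absorptivities in absorbance units
#' per ug/mL, sized so a 10 ug/mL analyte solution peaks near 0.5-0.9 AU.
#'
#' @return named list of data frames with columns `center`, `width`,
#'   `amplitude`.
#' @export
pure_band_params <- function() {
  list(
    PYR = data.frame(center = c(290, 254, 228),
                     width  = c(16,  18,  8),
                     amplitude = c(0.065, 0.018, 0.030)),
    CYC = data.frame(center = c(225, 262),
                     width  = c(10,  22),
                     amplitude = c(0.090, 0.016)),
    MEC = data.frame(center = c(230, 268),
                     width  = c(11,  24),
                     amplitude = c(0.085, 0.020)),
    BEH = data.frame(center = c(226, 258),
                     width  = c(12,  26),
                     amplitude = c(0.060, 0.024)),
    BEP = data.frame(center = c(254, 228),
                     width  = c(26,  9),
                     amplitude = c(0.070, 0.028))
  )
}

#' Default pure-component spectra on a grid
#'
#' Samples the Gaussian-band absorptivities of [pure_band_params()] on
#' `grid` and verifies that each analyte's absorption maximum falls at its
#' declared wavelength (within one grid step) and that the five spectra are
#' linearly independent.
#'
#' @param grid a [wavelength_grid()] covering 221-370 nm.
#' @param bands band parameter list as from [pure_band_params()].
#' @return components x points matrix of absorptivities (AU per ug/mL) with
#'   component row names; the grid is attached as attribute `"grid"`.
#' @export
default_pure_spectra <- function(grid = wavelength_grid(),
                                 bands = pure_band_params()) {
  lambda_max <- c(PYR = 290, CYC = 225, MEC = 230)
  needed <- unlist(lapply(bands, `[[`, "center"))
  if (grid$start > min(lambda_max) || grid$stop < max(lambda_max)) {
    stop("grid too narrow: it must contain the declared absorption maxima (",
         paste(lambda_max, collapse = ", "), " nm)", call. = FALSE)
  }
  S <- t(vapply(bands, function(b) {
    rowSums(vapply(seq_len(nrow(b)), function(i) {
      gaussian_band(grid$nm, b$center[i], b$width[i], b$amplitude[i])
    }, numeric(grid$points)))
  }, numeric(grid$points)))
  rownames(S) <- names(bands)
  S <- S[mixture_components()[mixture_components() %in% rownames(S)], ,
         drop = FALSE]
  for (comp in names(lambda_max)) {
    got <- grid$nm[which.max(S[comp, ])]
    if (abs(got - lambda_max[[comp]]) > grid$step) {
      stop("configuration error: ", comp, " maximum at ", got,
           " nm, expected ", lambda_max[[comp]], " nm", call. = FALSE)
    }
  }
  if (any(S < 0)) stop("pure spectra must be non-negative", call. = FALSE)
  if (numerical_rank(S) < nrow(S)) {
    stop("pure spectra are not linearly independent on this grid",
         call. = FALSE)
  }
  attr(S, "grid") <- grid
  S
}

#' Artifact configuration for the spectra simulator
#'
#' All artifact scales default to zero so that simulated data are exactly
#' linear in the concentrations; comparison experiments switch them on.
#'
#' @param noise_sd standard deviation of additive iid Gaussian noise (AU).
#' @param baseline_rank number of independent polynomial baseline-drift
#'   shapes (degree 1..`baseline_rank`, each unit-norm); each sample gets its
#'   own Gaussian amplitude for each shape, so the planted
#'   concentration-independent structure has exactly this rank.
#' @param baseline_scale standard deviation of the baseline amplitudes (AU).
#' @param scatter_sd standard deviation of the per-sample multiplicative
#'   scatter factor (dimensionless; each spectrum is scaled by
#'   `1 + scatter`).
#' @param interferent optional pure spectrum (numeric vector on the grid) of
#'   an unmodelled absorbing species added with per-sample random amounts.
#' @param interferent_scale scale (ug/mL-like) of the half-normal per-sample
#'   interferent amounts.
#' @param seed integer seed making every draw reproducible.
#' @return object of class `artifact_config`.
#' @export
artifact_config <- function(noise_sd = 0, baseline_rank = 0,
                            baseline_scale = 0, scatter_sd = 0,
                            interferent = NULL, interferent_scale = 0,
                            seed = 1L) {
  stopifnot(noise_sd >= 0, scatter_sd >= 0, baseline_scale >= 0,
            baseline_rank >= 0, interferent_scale >= 0)
  structure(list(noise_sd = noise_sd, baseline_rank = baseline_rank,
                 baseline_scale = baseline_scale, scatter_sd = scatter_sd,
                 interferent = interferent,
                 interferent_scale = interferent_scale,
                 seed = as.integer(seed)),
            class = "artifact_config")
}

# Unit-norm polynomial drift shapes of degree 1..rank on x in [-1, 1]
baseline_shapes <- function(grid, rank) {
  x <- seq(-1, 1, length.out = grid$points)
  shapes <- vapply(seq_len(rank), function(d) {
    v <- x^d
    v / vnorm(v)
  }, numeric(grid$points))
  matrix(shapes, nrow = grid$points)
}

# Run `expr` under a local RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Beer-Lambert mixing of pure spectra with optional artifacts
#'
#' Computes `A = C %*% S`, adds the configured baseline drift and
#' interferent contribution, scales each sample by `1 + scatter`, then adds
#' iid Gaussian noise.  With all artifact scales zero the result equals
#' `C %*% S` exactly.
#'
#' @param C samples x components concentration matrix (ug/mL), non-negative.
#' @param S components x points pure-spectra matrix (as from
#'   [default_pure_spectra()]); if both `C` and `S` carry component names
#'   they must agree in order.
#' @param artifacts an [artifact_config()].
#' @param grid the wavelength grid (default: taken from `S`).
#' @return samples x points absorbance matrix with the grid attached as
#'   attribute `"grid"` and sample ids as row names.
#' @export
mix_spectra <- function(C, S, artifacts = artifact_config(),
                        grid = attr(S, "grid")) {
  C <- as.matrix(C)
  if (any(C < 0)) stop("negative concentrations are not allowed",
                       call. = FALSE)
  if (ncol(C) != nrow(S)) {
    stop("component count of C (", ncol(C), ") does not match S (",
         nrow(S), ")", call. = FALSE)
  }
  if (!is.null(colnames(C)) && !is.null(rownames(S)) &&
      !identical(colnames(C), rownames(S))) {
    stop("component order of C does not match S", call. = FALSE)
  }
  if (is.null(grid)) stop("a wavelength grid is required", call. = FALSE)
  n <- nrow(C)
  p <- grid$points
  A <- C %*% S
  with_local_seed(artifacts$seed, {
    if (artifacts$baseline_rank > 0 && artifacts$baseline_scale > 0) {
      shapes <- baseline_shapes(grid, artifacts$baseline_rank)
      amps <- matrix(stats::rnorm(n * artifacts$baseline_rank,
                                  sd = artifacts$baseline_scale),
                     n, artifacts$baseline_rank)
      A <- A + amps %*% t(shapes)
    }
    if (!is.null(artifacts$interferent) && artifacts$interferent_scale > 0) {
      stopifnot(length(artifacts$interferent) == p)
      amount <- abs(stats::rnorm(n)) * artifacts$interferent_scale
      A <- A + amount %*% t(as.numeric(artifacts$interferent))
    }
    if (artifacts$scatter_sd > 0) {
      A <- A * (1 + stats::rnorm(n, sd = artifacts$scatter_sd))
    }
    if (artifacts$noise_sd > 0) {
      A <- A + matrix(stats::rnorm(n * p, sd = artifacts$noise_sd), n, p)
    }
  })
  dimnames(A) <- list(sprintf("S%02d", seq_len(n)), grid$nm)
  attr(A, "grid") <- grid
  A
}

#' Generate a paired (spectra, concentrations) dataset
#'
#' @param x a `calibration_design`, a `validation_set`, or a concentration
#'   matrix.
#' @param S pure-spectra matrix.
#' @param artifacts an [artifact_config()]; regeneration with the same seed
#'   is bit-identical.
#' @return object of class `uv_dataset`: list with `spectra`,
#'   `concentrations`, and (when `x` is a validation set) `position`.
#' @export
generate_dataset <- function(x, S = default_pure_spectra(),
                             artifacts = artifact_config()) {
  position <- NULL
  if (inherits(x, "calibration_design")) {
    C <- x$concentrations
  } else if (inherits(x, "validation_set")) {
    C <- x$concentrations
    position <- x$position
  } else {
    C <- as.matrix(x)
  }
  A <- mix_spectra(C, S, artifacts)
  structure(list(spectra = A, concentrations = C, position = position,
                 artifacts = artifacts),
            class = "uv_dataset")
}

#' Write / read a spectra matrix as CSV
#'
#' First column `sample`, remaining columns one per wavelength with the
#' wavelength (nm) as header.
#'
#' @param A samples x points absorbance matrix with a `"grid"` attribute.
#' @param path output file.
#' @return `path` invisibly (write); the absorbance matrix with its grid
#'   reconstructed from the headers (read).
#' @export
write_spectra_csv <- function(A, path) {
  d <- data.frame(sample = rownames(A), A, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  A <- as.matrix(d[, -1, drop = FALSE])
  rownames(A) <- d$sample
  nm <- as.numeric(colnames(A))
  step <- diff(nm)[1]
  attr(A, "grid") <- wavelength_grid(min(nm), max(nm), step)
  A
}
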