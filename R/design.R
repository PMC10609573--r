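# Five-level, five-factor cyclic calibration design for the quinary
# PYR/CYC/MEC/BEP/BEH mixture, plus the fixed validation set.

#' Component names of the quinary mixture
#'
#' Three analytes -- pyridoxine HCl (PYR), cyclizine HCl (CYC) and meclizine
#' HCl (MEC) -- and two related impurities: benzhydrol (BEH, the cyclizine
#' impurity) and 4-chlorobenzophenone (BEP, the meclizine impurity).
#'
#' @return character vector of the five component names, in design order.
#' @export
mixture_components <- function() c("PYR", "CYC", "MEC", "BEP", "BEH")

#' Component roles (analyte or impurity)
#'
#' @return named character vector mapping each component to its role.
#' @export
component_roles <- function() {
  c(PYR = "analyte", CYC = "analyte", MEC = "analyte",
    BEP = "impurity", BEH = "impurity")
}

#' Default cyclic generator sequence of the calibration design
#'
#' A length-24 sequence over the level codes \{-2, -1, 0, 1, 2\} in which
#' each non-zero code appears five times and 0 appears four times.  Rows
#' 2..25 of the coded design are consecutive length-5 windows read cyclically
#' from this sequence; together with the all-centre first row this balances
#' every level five times in every column.
#'
#' @return integer vector of length 24.
#' @export
design_generator <- function() {
  c(0L, -2L, -2L, 2L, -1L, 2L, 0L, -1L, -1L, 1L, 2L, 1L,
    0L, 2L, 2L, -2L, 1L, -2L, 0L, 1L, 1L, -1L, -2L, -1L)
}

#' Map the five level codes of one component to concentrations
#'
#' Level code `k` maps to `center + k * step` (ug/mL).  The centre level is
#' code 0; codes run over -2..2.
#'
#' @param component component name.
#' @param center centre-level concentration (ug/mL), must exceed `2 * step`
#'   so the lowest level stays positive.
#' @param step concentration increment between adjacent levels (ug/mL).
#' @return an object of class `level_map` with fields `component`, `center`,
#'   `step`, `codes` and `concentrations`.
#' @examples
#' build_level_map("PYR", center = 10, step = 2.5)
#' @export
build_level_map <- function(component, center, step) {
  stopifnot(is.character(component), length(component) == 1L,
            is.numeric(center), length(center) == 1L,
            is.numeric(step), length(step) == 1L, step > 0)
  codes <- -2L:2L
  conc <- center + codes * step
  if (any(conc <= 0)) {
    stop("invalid design: level map for '", component,
         "' yields non-positive concentration at code ",
         paste(codes[conc <= 0], collapse = ", "),
         " (center must exceed 2 * step)", call. = FALSE)
  }
  structure(
    list(component = component, center = center, step = step,
         codes = codes, concentrations = conc),
    class = "level_map"
  )
}

#' Default level maps of the study design
#'
#' Centre levels are 10 ug/mL for PYR and MEC and 8.5 ug/mL for CYC; both
#' impurities are centred at 0.25 ug/mL with 0.05 ug/mL steps, keeping them
#' far below the analytes as impurity specifications require.
#'
#' @return named list of [build_level_map()] objects in design order.
#' @export
default_level_maps <- function() {
  list(
    PYR = build_level_map("PYR", 10,   2.5),
    CYC = build_level_map("CYC", 8.5,  2),
    MEC = build_level_map("MEC", 10,   2.5),
    BEP = build_level_map("BEP", 0.25, 0.05),
    BEH = build_level_map("BEH", 0.25, 0.05)
  )
}

#' Generate the 25-sample cyclic multilevel calibration design
#'
#' Row 1 is the all-centre mixture (all codes 0); rows 2..25 are consecutive
#' length-5 windows over the cyclic `generator` sequence, so column j + 1 of
#' one row reappears as column j of the next.  Every column contains each of
#' the five level codes exactly five times.
#'
#' @param level_maps named list of [build_level_map()] objects, one per
#'   component (design order).
#' @param generator length-24 integer sequence over \{-2,...,2\} in which each
#'   non-zero code appears exactly five times and 0 four times.  The default
#'   reproduces the study's training design.
#' @return an object of class `calibration_design`: list with `coded` (25 x 5
#'   integer matrix), `level_maps`, and `concentrations` (25 x 5, ug/mL).
#' @examples
#' d <- generate_design(default_level_maps())
#' d$concentrations[14, ]  # mixture 14
#' @export
generate_design <- function(level_maps = default_level_maps(),
                            generator = design_generator()) {
  k <- length(level_maps)
  stopifnot(k >= 1L)
  generator <- as.integer(generator)
  n_gen <- length(generator)
  counts <- table(factor(generator, levels = -2:2))
  expected <- c(`-2` = 5L, `-1` = 5L, `0` = n_gen - 20L, `1` = 5L, `2` = 5L)
  if (n_gen != 24L || !all(counts == expected)) {
    stop("invalid design: generator must have length 24 with codes ",
         "-2, -1, 1, 2 appearing 5 times each and 0 appearing 4 times",
         call. = FALSE)
  }
  coded <- rbind(
    rep(0L, k),
    t(vapply(seq_len(n_gen),
             function(i) generator[((i - 1L) + 0:(k - 1L)) %% n_gen + 1L],
             integer(k)))
  )
  comp <- unname(vapply(level_maps, `[[`, "", "component"))
  colnames(coded) <- comp
  conc <- vapply(seq_len(k), function(j) {
    level_maps[[j]]$center + coded[, j] * level_maps[[j]]$step
  }, numeric(nrow(coded)))
  colnames(conc) <- comp
  design <- structure(
    list(coded = coded, level_maps = level_maps, concentrations = conc),
    class = "calibration_design"
  )
  validate_design(design)
  design
}

#' Validate the structural invariants of a calibration design
#'
#' Checks dimensions, the five-per-level balance of every column, the
#' all-centre first row, the cyclic-shift relation between consecutive rows,
#' and positivity of all concentrations.
#'
#' @param design a `calibration_design`.
#' @return the design, invisibly; stops on violation.
#' @export
validate_design <- function(design) {
  coded <- design$coded
  if (!all(dim(coded) == c(25L, 5L))) {
    stop("invalid design: expected 25 rows and 5 columns", call. = FALSE)
  }
  balanced <- apply(coded, 2L, function(x) {
    all(table(factor(x, levels = -2:2)) == 5L)
  })
  if (!all(balanced)) {
    stop("invalid design: each column must contain every level code ",
         "exactly 5 times", call. = FALSE)
  }
  if (any(coded[1L, ] != 0L)) {
    stop("invalid design: row 1 must be the all-centre mixture", call. = FALSE)
  }
  for (i in 2:24) {
    if (any(coded[i + 1L, 1:4] != coded[i, 2:5])) {
      stop("invalid design: cyclic-shift property violated between rows ",
           i, " and ", i + 1L, call. = FALSE)
    }
  }
  if (any(design$concentrations <= 0)) {
    stop("invalid design: non-positive concentration", call. = FALSE)
  }
  invisible(design)
}

#' The training design of the study as printed (fixture)
#'
#' Returns the 25 x 5 concentration matrix of the training mixtures verbatim.
#' [generate_design()] with the default generator reproduces it exactly.
#'
#' @return numeric matrix, 25 samples x 5 components (ug/mL).
#' @export
training_design_table <- function() {
  path <- system.file("extdata", "training_design.csv", package = "augcls",
                      mustWork = TRUE)
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  rownames(m) <- NULL
  m
}

#' The 16-sample validation set as printed (fixture)
#'
#' Eight mixtures lie inside the calibration concentration space ("IN") and
#' eight deliberately outside it ("OUT"), probing generalisation to
#' unplanned samples.
#'
#' @return an object of class `validation_set`: list with `concentrations`
#'   (16 x 5 matrix, ug/mL) and `position` (character, "IN"/"OUT").
#' @export
validation_set_table <- function() {
  path <- system.file("extdata", "validation_set.csv", package = "augcls",
                      mustWork = TRUE)
  d <- utils::read.csv(path, check.names = FALSE)
  conc <- as.matrix(d[, mixture_components()])
  rownames(conc) <- NULL
  vs <- structure(
    list(concentrations = conc, position = as.character(d$position)),
    class = "validation_set"
  )
  stopifnot(sum(vs$position == "IN") == 8L, sum(vs$position == "OUT") == 8L)
  vs
}

#' Write / read a concentration design as CSV
#'
#' Header row of component names, one row per mixture, values in ug/mL.
#'
#' @param concentrations samples x components numeric matrix.
#' @param path output file.
#' @return `path`, invisibly (write) or the concentration matrix (read).
#' @export
write_design_csv <- function(concentrations, path) {
  utils::write.csv(as.data.frame(concentrations), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  rownames(m) <- NULL
  m
}
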