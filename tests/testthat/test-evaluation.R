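test_that("recovery and rmse primitives are correct", {
  expect_equal(recovery_percent(c(10, 8), c(10, 4)), c(100, 50))
  expect_error(recovery_percent(c(0, 1), c(1, 1)), "positive")
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_equal(rmse(c(0, 0), c(3, 4), divisor = 1), 5)
  expect_error(rmse(1:3, 1:2), "equal length")
  st <- summarize_recoveries(c(99, 101, 100))
  expect_equal(st$mean, 100)
  expect_equal(st$sd, sd(c(99, 101, 100)))
  expect_error(summarize_recoveries(100), "at least two")
})

test_that("pooled_t and variance_ratio match stats-package oracles", {
  set.seed(14)
  x <- rnorm(6, 100, 2); y <- rnorm(6, 99, 2.5)
  got <- pooled_t(mean(x), sd(x), 6, mean(y), sd(y), 6)
  oracle <- unname(t.test(x, y, var.equal = TRUE)$statistic)
  expect_equal(got, oracle, tolerance = 1e-10)
  expect_equal(variance_ratio(sd(x), sd(y)),
               max(var(x), var(y)) / min(var(x), var(y)),
               tolerance = 1e-10)
  expect_equal(variance_ratio(2, 3), variance_ratio(3, 2))
  expect_gte(variance_ratio(1.7, 2.9), 1)
  expect_error(variance_ratio(0, 1), "positive")
  # degenerate pooled variance
  expect_equal(pooled_t(5, 0, 3, 5, 0, 3), 0)
  expect_warning(t0 <- pooled_t(6, 0, 3, 5, 0, 3), "zero pooled variance")
  expect_identical(t0, Inf)
})

test_that("compare_methods applies the p = 0.05 critical values", {
  cmp <- compare_methods(100.1, 1.5, 6, 100.0, 1.4, 6)
  expect_equal(cmp$t_crit, qt(0.975, 10))
  expect_equal(cmp$F_crit, qf(0.95, 5, 5))
  expect_false(cmp$t_significant)
  expect_false(cmp$F_significant)
  big <- compare_methods(110, 1.5, 6, 100, 1.4, 6)
  expect_true(big$t_significant)
})

test_that("evaluate_run produces consistent per-sample and summary blocks", {
  ds <- artifact_study(rank = 2L)
  n_factors <- list(osc = c(2L, 2L, 2L), dosc = c(2L, 2L, 2L),
                    nap = c(6L, 6L, 6L))
  models <- fit_comparison_models(ds$calibration$spectra,
                                  ds$calibration$concentrations, n_factors)
  rep <- evaluate_run(models, ds$calibration, ds$validation)
  # 4 models x 3 analytes x (25 + 16) samples
  expect_identical(nrow(rep$samples), 4L * 3L * 41L)
  expect_setequal(unique(rep$summary$subset),
                  c("training", "IN", "OUT", "validation-all"))
  expect_setequal(unique(rep$summary$model), c("CLS", "OSC", "DOSC", "NAP"))
  # augmented models are exact on noiseless artifact data
  aug <- rep$summary[rep$summary$model == "DOSC", ]
  expect_true(all(abs(aug$mean_recovery - 100) < 1e-6))
  expect_true(all(aug$rmse < 1e-6))
  # summary rows agree with direct recomputation from the sample rows
  blk <- rep$samples[rep$samples$model == "CLS" &
                       rep$samples$analyte == "PYR" &
                       rep$samples$subset == "training", ]
  row <- rep$summary[rep$summary$model == "CLS" &
                       rep$summary$analyte == "PYR" &
                       rep$summary$subset == "training", ]
  expect_equal(row$mean_recovery, mean(blk$recovery))
  expect_equal(row$rmse, rmse(blk$taken, blk$predicted, divisor = 25))
  expect_output(print(rep), "Evaluation report")
})

test_that("evaluation reports round-trip through CSV", {
  ds <- artifact_study(rank = 1L)
  models <- fit_comparison_models(
    ds$calibration$spectra, ds$calibration$concentrations,
    list(osc = c(1L, 1L, 1L), dosc = c(1L, 1L, 1L), nap = c(5L, 5L, 5L)))
  rep <- evaluate_run(models, ds$calibration, ds$validation)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  p3 <- withr::local_tempfile(fileext = ".json")
  write_evaluation_report(rep, p1, p2, p3)
  back <- utils::read.csv(p1)
  expect_identical(nrow(back), nrow(rep$samples))
  expect_equal(back$recovery, rep$samples$recovery, tolerance = 1e-6)
  expect_true(jsonlite::validate(paste(readLines(p3), collapse = "\n")))
})

test_that("replayed training summaries match the published table", {
  tr <- replay_training_table()
  expect_identical(nrow(tr), 12L)
  expect_true(all(tr$n == 25L))
  cell <- function(a, m) tr[tr$analyte == a & tr$model == m, ]
  # printed at 2 dp (means) / 3 dp (RMSEC); absolute half-ulp tolerances
  expect_lt(abs(cell("PYR", "CLS")$mean_recovery - 100.10), 0.0055)
  expect_lt(abs(cell("CYC", "CLS")$mean_recovery - 99.73), 0.0055)
  expect_lt(abs(cell("MEC", "CLS")$mean_recovery - 100.72), 0.0055)
  expect_lt(abs(cell("PYR", "CLS")$rmsec - 0.109), 0.0015)
  expect_lt(abs(cell("CYC", "CLS")$rmsec - 0.374), 0.0015)
  expect_lt(abs(cell("MEC", "CLS")$rmsec - 0.454), 0.0015)
  # augmented models beat plain CLS on every analyte
  for (a in c("PYR", "CYC", "MEC")) {
    for (m in c("OSC", "DOSC", "NAP")) {
      expect_lt(cell(a, m)$rmsec, cell(a, "CLS")$rmsec)
    }
  }
})

test_that("replayed validation summaries match the published table", {
  va <- replay_validation_table()
  expect_identical(nrow(va), 24L)
  expect_true(all(va$n == 8L))
  cell <- function(a, m, s) va[va$analyte == a & va$model == m &
                                 va$subset == s, ]
  expect_lt(abs(cell("PYR", "CLS", "IN")$mean_recovery - 98.14), 0.0055)
  expect_lt(abs(cell("MEC", "CLS", "OUT")$mean_recovery - 87.52), 0.0055)
  expect_lt(abs(cell("MEC", "CLS", "OUT")$sd_recovery - 12.71), 0.0055)
  expect_lt(abs(cell("PYR", "CLS", "OUT")$rmsep - 0.283), 0.0015)
  expect_lt(abs(cell("CYC", "DOSC", "OUT")$rmsep - 0.197), 0.0015)
  expect_true(all(is.na(va$rmsep[va$subset == "IN"])))
  # extrapolation penalty: CYC and MEC degrade sharply for plain CLS
  expect_gt(cell("CYC", "CLS", "OUT")$rmsep,
            3 * cell("CYC", "DOSC", "OUT")$rmsep)
  expect_gt(cell("MEC", "CLS", "OUT")$rmsep,
            3 * cell("MEC", "DOSC", "OUT")$rmsep)
})

test_that("replayed method comparison reproduces the reference t and F cell", {
  cmp <- replay_method_comparison()
  expect_identical(nrow(cmp), 16L)
  expect_true(all(abs(cmp$t_crit - qt(0.975, 10)) < 1e-9))
  expect_true(all(abs(cmp$F_crit - qf(0.95, 5, 5)) < 1e-9))
  expect_true(all(cmp$F >= 1))
  row <- cmp[cmp$formulation == "Emetrex" & cmp$analyte == "PYR" &
               cmp$method == "CLS", ]
  expect_equal(abs(row$t), 2.200, tolerance = 0.01)
  expect_equal(row$F, 1.320, tolerance = 0.01)
  expect_lt(abs(row$t), row$t_crit)
  expect_lt(row$F, row$F_crit)
  # no method shows a significant variance difference from the reference
  expect_true(all(cmp$F < cmp$F_crit))
  all_tabs <- replay_published_tables()
  expect_named(all_tabs, c("training", "validation", "comparison"))
})
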