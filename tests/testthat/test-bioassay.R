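test_that("radical-scavenging percentages match hand arithmetic", {
  expect_equal(scavenging_percent(absorbance_triple(0.8, 0.8, 0)), 0)
  expect_equal(scavenging_percent(absorbance_triple(0.8, 0.4, 0.1)), 62.5)
  # perfect quench: sample signal equals its own blank
  expect_equal(scavenging_percent(absorbance_triple(0.7, 0.25, 0.25)), 100)
  expect_error(scavenging_percent(absorbance_triple(0, 0.4, 0.1)),
               class = "lipidqi_assay_error")
  # out-of-range values are reported as-is, with a warning
  expect_warning(v <- scavenging_percent(absorbance_triple(0.5, 0.9, 0)),
                 "outside")
  expect_lt(v, 0)
})

test_that("scavenging is invariant under joint rescaling of absorbances", {
  for (c_scale in c(0.1, 1, 7.3)) {
    expect_equal(
      scavenging_percent(absorbance_triple(0.8 * c_scale, 0.4 * c_scale,
                                           0.1 * c_scale)),
      62.5, tolerance = 1e-12)
  }
})

test_that("ACE inhibition follows the blank-corrected standard form", {
  expect_equal(ace_inhibition_percent(absorbance_triple(1.0, 0.2, 0.2, 0.2)), 100)
  expect_equal(ace_inhibition_percent(absorbance_triple(1.0, 1.0, 0.2, 0.2)), 0)
  expect_equal(ace_inhibition_percent(absorbance_triple(1.0, 0.6, 0.2, 0.2)), 50)
  expect_error(ace_inhibition_percent(absorbance_triple(0.2, 0.6, 0.2, 0.2)),
               class = "lipidqi_assay_error")
})

test_that("dose_response validates its inputs", {
  expect_error(dose_response(c(1, 2), c(10, 20, 30)), class = "lipidqi_assay_error")
  expect_error(dose_response(c(-1, 2, 3), c(1, 2, 3)), class = "lipidqi_assay_error")
  expect_error(dose_response(c(1, 1, 2), c(1, 2, 3)), class = "lipidqi_assay_error")
  d <- dose_response(c(0.5, 1, 2), c(20, 50, 80), unit = "ug/mL")
  expect_identical(attr(d, "unit"), "ug/mL")
})

test_that("an exact 50% point is returned verbatim by interpolation", {
  d <- dose_response(c(1, 2, 4), c(25, 50, 75))
  est <- estimate_ic50(d, method = "interpolation")
  expect_equal(est$ic50, 2)
  expect_identical(est$method, "interpolation")
})

test_that("noise-free 4PL curves are recovered to 1e-6 relative", {
  doses <- 0.2 * 2^seq(-3.5, 3.5, 1)   # 8 doses spanning the midpoint
  d <- simulate_dose_response(doses, ic50 = 0.2, hill = 1.5)
  est <- estimate_ic50(d)
  expect_identical(est$method, "logistic-fit")
  expect_lt(abs(est$ic50 - 0.2) / 0.2, 1e-6)
  expect_named(est$fit_params, c("bottom", "top", "ic50", "hill"))
  expect_equal(unname(est$fit_params[["hill"]]), 1.5, tolerance = 1e-4)
})

test_that("inverted (decreasing) series are handled by sign detection", {
  doses <- 2^seq(-2, 3)
  act_up <- 100 / (1 + (1.7 / doses)^2)      # increasing, midpoint 1.7
  d_down <- dose_response(doses, 100 - act_up)
  est <- estimate_ic50(d_down)
  expect_equal(est$ic50, 1.7, tolerance = 1e-5)
  # interpolation route finds the downward crossing too
  est2 <- estimate_ic50(d_down, method = "interpolation")
  expect_true(est2$ic50 >= min(doses) && est2$ic50 <= max(doses))
})

test_that("series never crossing 50% yield a diagnostic no-estimate error", {
  d <- dose_response(c(1, 2, 4), c(5, 8, 11))
  expect_error(estimate_ic50(d), class = "lipidqi_no_estimate_error")
  expect_error(estimate_ic50(d), "never cross 50")
})

test_that("interpolation and logistic fit agree on dense noise-free curves", {
  doses <- 0.5 * 2^seq(-3, 3, length.out = 13)
  d <- simulate_dose_response(doses, ic50 = 0.5, hill = 1.2)
  fit <- estimate_ic50(d, method = "logistic")
  lin <- estimate_ic50(d, method = "interpolation")
  expect_lt(abs(fit$ic50 - lin$ic50) / fit$ic50, 0.05)
})

test_that("noisy replicates recover IC50 within 10% median relative error", {
  # scaled-down version of the acceptance-grade run (25 of 100 replicates)
  doses <- 0.2 * 2^seq(-3, 3, 1)
  err <- vapply(1:25, function(s) {
    d <- simulate_dose_response(doses, ic50 = 0.2, hill = 1.5,
                                noise_sd = 3, seed = 1000 + s)
    est <- estimate_ic50(d)
    abs(est$ic50 - 0.2) / 0.2
  }, numeric(1))
  expect_lt(stats::median(err), 0.10)
})

test_that("plate CSVs load, reject mixed units, and evaluate end-to-end", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  act <- 100 / (1 + (2 / (2^seq(-2, 3)))^1.5)
  plate <- data.frame(concentration = 2^seq(-2, 3), unit = "mg/mL",
                      a_control = 0.9, a_sample = 0.9 * (1 - act / 100),
                      a_sample_blank = 0)
  write.csv(plate, tmp, row.names = FALSE)
  loaded <- read_plate_csv(tmp)
  expect_identical(attr(loaded, "unit"), "mg/mL")
  res <- evaluate_plate(loaded, assay = "dpph")
  expect_equal(res$doses$activity, act, tolerance = 1e-9)
  expect_equal(res$ic50$ic50, 2, tolerance = 1e-4)

  plate$unit[2] <- "ug/mL"
  write.csv(plate, tmp, row.names = FALSE)
  expect_error(read_plate_csv(tmp), class = "lipidqi_assay_error",
               regexp = "mixed")
})
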