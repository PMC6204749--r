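truth_curve <- new_calibration_curve(G0 = 20, Gmax = 170, tau = 500 / log(20))

test_that("predict_gray follows the exponential-saturation form", {
  expect_equal(predict_gray(truth_curve, 0), 20)
  expect_equal(predict_gray(truth_curve, truth_curve$tau * log(20)),
               20 + 0.95 * 150)
  # monotone approach to the asymptote
  cs <- seq(0, 5000, by = 50)
  g <- predict_gray(truth_curve, cs)
  expect_true(all(diff(g) > 0))
  expect_lt(170 - predict_gray(truth_curve, 1e6), 1e-9)
  expect_error(predict_gray(truth_curve, -1), "non-negative")
})

test_that("fit_calibration recovers exact parameters from noiseless standards", {
  std <- gen_standards(seq(0, 1000, by = 50), truth = default_truth,
                       noise_sd = 0, seed = 1)
  curve <- fit_calibration(std)
  expect_equal(curve$G0, 20, tolerance = 1e-6)
  expect_equal(curve$Gmax, 170, tolerance = 1e-6)
  expect_equal(curve$tau, 500 / log(20), tolerance = 1e-6)
  expect_equal(curve$C_sat95, curve$tau * log(20))
  expect_equal(curve$r_squared, 1, tolerance = 1e-9)
})

test_that("fit_calibration recovers tau within 15% under default noise", {
  errs <- vapply(1:20, function(seed) {
    std <- gen_standards(seq(0, 1000, by = 50), truth = default_truth,
                         seed = seed)
    abs(fit_calibration(std)$tau - default_truth$curve$tau) /
      default_truth$curve$tau
  }, numeric(1))
  expect_true(all(errs < 0.15))
})

test_that("fit_calibration enforces its design preconditions", {
  # too few distinct concentrations
  std3 <- gen_standards(c(0, 200, 400), truth = default_truth, seed = 1)
  expect_error(fit_calibration(std3), ">= 4 distinct concentrations")
  # no anchor near saturation
  stdlow <- gen_standards(c(0, 50, 100, 150), truth = default_truth,
                          seed = 1)
  expect_error(fit_calibration(stdlow), ">= 4 distinct")
  # decreasing means over the lower half of the range
  bad <- tibble::tibble(
    concentration_ppm = rep(c(0, 100, 200, 300, 500), each = 2),
    gray = rep(c(100, 80, 60, 120, 140), each = 2))
  expect_error(fit_calibration(bad), "non-monotone standards")
})

test_that("invert_calibration is the exact inverse below the censoring point", {
  for (c_true in c(1, 50, 250, 400, 490)) {
    inv <- invert_calibration(truth_curve, predict_gray(truth_curve, c_true))
    expect_equal(inv$ppm, c_true, tolerance = 1e-9)
    expect_equal(inv$censored, "none")
  }
  expect_equal(invert_calibration(truth_curve, 20), list(ppm = 0,
                                                         censored = "none"))
})

test_that("invert_calibration censors at saturation and flags blank signals", {
  at95 <- invert_calibration(truth_curve, 20 + 0.95 * 150)
  expect_equal(at95$ppm, truth_curve$C_sat95)
  expect_equal(at95$censored, "above_saturation")
  expect_equal(invert_calibration(truth_curve, 170)$censored,
               "above_saturation")

  noisy <- new_calibration_curve(20, 170, 166.9, residual_sd = 1.5)
  # slightly below baseline clamps to zero; far below errors
  expect_equal(invert_calibration(noisy, 19)$ppm, 0)
  expect_error(invert_calibration(noisy, 15), "signal below blank")
})

test_that("temperature model recovers the printed drift line", {
  # exact line through the anchors plus midpoint: slope (96-82)/(50-25)
  pairs <- tibble::tibble(temperature_c = c(25, 37.5, 50),
                          gray = c(82, 89, 96))
  m <- fit_temperature_model(pairs)
  expect_equal(m$slope, 0.56, tolerance = 1e-12)
  expect_equal(m$reference_temp, 25)
  expect_equal(m$r_squared, 1)

  flat <- tibble::tibble(temperature_c = c(25, 30, 35), gray = c(90, 90, 90))
  expect_equal(fit_temperature_model(flat)$slope, 0)

  expect_error(fit_temperature_model(pairs[1:2, ]), ">= 3 distinct")
})

test_that("temperature-model slope recovery under noise stays within 20%", {
  slopes <- vapply(1:20, function(seed) {
    fit_temperature_model(gen_temperature(truth = default_truth,
                                          seed = seed))$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.56) / 0.56, 0.2)
  expect_true(mean(abs(slopes - 0.56) / 0.56 < 0.2) >= 0.8)
})

test_that("correct_temperature removes the linear drift", {
  m <- fit_temperature_model(tibble::tibble(
    temperature_c = c(25, 37.5, 50), gray = c(82, 89, 96)))
  expect_equal(correct_temperature(96, 50, m), 82)
  expect_equal(correct_temperature(123, 25, m), 123)  # at reference: no-op
  expect_warning(out <- correct_temperature(1, 80, m), "clamped")
  expect_equal(out, 0)
  # noiseless generated drift corrects back to the reference gray exactly
  tser <- gen_temperature(truth = default_truth, noise_sd = 0, seed = 1)
  m2 <- fit_temperature_model(tser)
  expect_equal(correct_temperature(tser$gray, tser$temperature_c, m2),
               rep(82, nrow(tser)), tolerance = 1e-9)
})

test_that("calibration and temperature models survive JSON round trips", {
  std <- gen_standards(seq(0, 1000, by = 100), truth = default_truth,
                       seed = 4)
  curve <- fit_calibration(std)
  f <- withr::local_tempfile(fileext = ".json")
  write_calibration(curve, f)
  back <- read_calibration(f)
  expect_equal(back$tau, curve$tau)
  expect_equal(back$C_sat95, curve$C_sat95)
  expect_equal(back$residual_sd, curve$residual_sd)

  m <- fit_temperature_model(gen_temperature(truth = default_truth,
                                             seed = 2))
  f2 <- withr::local_tempfile(fileext = ".json")
  write_temperature_model(m, f2)
  m2 <- read_temperature_model(f2)
  expect_equal(m2$slope, m$slope)
  expect_s3_class(m2, "temperature_model")
})

test_that("tidiers expose calibration fits as tibbles", {
  std <- gen_standards(seq(0, 1000, by = 100), truth = default_truth,
                       seed = 5)
  curve <- fit_calibration(std)
  td <- tidy(curve)
  expect_equal(td$term, c("G0", "Gmax", "tau"))
  gl <- glance(curve)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$C_sat95, curve$C_sat95)
  expect_s3_class(autoplot(curve), "ggplot")
})
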