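test_that("eliminate_outliers applies Tukey fences once and matches examples", {
  r <- eliminate_outliers(c(100, 101, 99, 100, 250))
  expect_setequal(r$values, c(100, 101, 99, 100))
  expect_equal(r$n_removed, 1L)

  # zero IQR retains all equal values
  r2 <- eliminate_outliers(rep(50, 5))
  expect_equal(r2$values, rep(50, 5))
  expect_equal(r2$n_removed, 0L)

  expect_error(eliminate_outliers(c(1, 2, 3, 4)), "too few pixels")
})

test_that("eliminate_outliers matches the brute-force fence oracle", {
  set.seed(7)
  for (i in 1:1000) {
    n <- sample(5:40, 1)
    v <- round(stats::rnorm(n, 100, 15) +
                 stats::rbinom(n, 1, 0.1) * 80, 2)
    got <- eliminate_outliers(v)
    keep <- oracle_tukey_keep(v)
    expect_identical(got$values, v[keep])
    expect_identical(got$n_removed, sum(!keep))
  }
})

test_that("eliminate_outliers is idempotent on spot pixel data", {
  for (seed in 1:10) {
    img <- gen_spot_image(200, default_truth, seed = seed)
    cmy <- to_cmy(rgb_to_gray(img))
    vals <- as.numeric(extract_roi(cmy, detect_spot_roi(cmy)))
    once <- eliminate_outliers(vals)
    expect_equal(eliminate_outliers(once$values)$n_removed, 0L)
  }
})

test_that("injected outlier pixels are removed at about their true rate", {
  fracs <- vapply(1:20, function(seed) {
    img <- gen_spot_image(200, default_truth, seed = seed)
    cmy <- to_cmy(rgb_to_gray(img))
    vals <- extract_roi(cmy, detect_spot_roi(cmy))
    eliminate_outliers(as.numeric(vals))$n_removed / length(vals)
  }, numeric(1))
  expect_gte(mean(fracs), 0.01)
  expect_lte(mean(fracs), 0.03)
})

test_that("mean_gray is the arithmetic mean", {
  expect_equal(mean_gray(c(100, 102, 104)), 102)
  expect_equal(mean_gray(7.5), 7.5)
  expect_error(mean_gray(numeric(0)), "no pixels")
  # spot mean lands within 3 standard errors of the generator truth
  img <- gen_spot_image(150, default_truth, outlier_fraction = 0,
                        seed = 21)
  cmy <- to_cmy(rgb_to_gray(img))
  vals <- as.numeric(extract_roi(cmy, detect_spot_roi(cmy)))
  g_true <- predict_gray(default_truth$curve, 150)
  se <- default_truth$pixel_sd / sqrt(length(vals))
  # rounding to 8-bit on write adds < 0.5 gray of quantization
  expect_lt(abs(mean_gray(vals) - g_true), 3 * se + 0.5)
})

test_that("estimate_concentration inverts, scales and censors", {
  curve <- new_calibration_curve(20, 170, 500 / log(20), residual_sd = 0.5)
  # baseline gray maps to 0 ppm
  est0 <- estimate_concentration(20, curve)
  expect_equal(est0$ppm, 0)
  expect_equal(est0$censored, "none")
  expect_equal(make_remark(est0$ppm), "below_range")

  # 95% of span censors at the saturation concentration x dilution
  est95 <- estimate_concentration(20 + 0.95 * 150, curve,
                                  dilution_factor = 2)
  expect_equal(est95$ppm, 2 * curve$C_sat95)
  expect_equal(est95$censored, "above_saturation")

  # round trip at 200 ppm diluted, dilution 2 -> 400 ppm undiluted
  g <- predict_gray(curve, 200)
  est <- estimate_concentration(g, curve, dilution_factor = 2)
  expect_equal(est$ppm, 400, tolerance = 1e-9)
  expect_gt(est$half_width, 0)

  expect_error(estimate_concentration(10, curve), "signal below blank")
  expect_error(estimate_concentration(100, curve, dilution_factor = 0.5),
               ">= 1")
})

test_that("estimate_concentration applies the temperature correction first", {
  curve <- new_calibration_curve(20, 170, 500 / log(20), residual_sd = 0.5,
                                 temperature_ref = 25)
  tm <- fit_temperature_model(tibble::tibble(
    temperature_c = c(25, 37.5, 50), gray = c(82, 89, 96)))
  g25 <- predict_gray(curve, 100)
  g50 <- g25 + 0.56 * 25  # same spot read at 50 degC drifts upward
  est <- estimate_concentration(g50, curve, dilution_factor = 1,
                                temperature_c = 50, temp_model = tm)
  expect_equal(est$ppm, 100, tolerance = 1e-9)
  # without the model the drift inflates the estimate
  est_raw <- estimate_concentration(g50, curve, dilution_factor = 1)
  expect_gt(est_raw$ppm, 110)
})

test_that("estimate_concentration is monotone in gray up to censoring", {
  curve <- new_calibration_curve(20, 170, 500 / log(20), residual_sd = 0.5)
  grays <- seq(20, 20 + 0.949 * 150, length.out = 100)
  ppm <- vapply(grays, function(g) estimate_concentration(g, curve)$ppm,
                numeric(1))
  expect_true(all(diff(ppm) >= 0))
})

test_that("make_remark uses the printed 300-700 ppm range inclusively", {
  expect_equal(make_remark(550), "within_acceptable_limit")
  expect_equal(make_remark(299.999), "below_range")
  expect_equal(make_remark(300), "within_acceptable_limit")
  expect_equal(make_remark(700), "within_acceptable_limit")
  expect_equal(make_remark(701), "above_acceptable_limit")
  expect_equal(make_remark(0), "below_range")
  expect_error(make_remark(-1), "non-negative")
})

test_that("quantify_image recovers generator truth end to end", {
  curve <- fit_calibration(gen_standards(seq(0, 1000, 50),
                                         truth = default_truth, seed = 101))
  img <- withr::local_tempfile(fileext = ".png")
  write_spot_png(gen_spot_image(100, default_truth, seed = 5), img)
  q <- quantify_image(img, curve)
  expect_s3_class(q, "quant_result")
  expect_equal(q$ppm, 200, tolerance = 0.1)  # dilution 2, 10% band
  expect_equal(q$remark, "below_range")
  expect_lt(q$n_outliers_removed, q$n_pixels_total)

  # blank spot reads 0 ppm
  write_spot_png(gen_spot_image(0, default_truth, noise_sd = 0,
                                outlier_fraction = 0, seed = 1), img)
  q0 <- quantify_image(img, curve)
  expect_lt(q0$ppm, 15)
  expect_equal(q0$remark, "below_range")

  # beyond saturation: censored lower bound
  write_spot_png(gen_spot_image(900, default_truth, seed = 6), img)
  qs <- quantify_image(img, curve)
  expect_equal(qs$censored, "above_saturation")
  expect_equal(qs$ppm, 2 * curve$C_sat95)
})

test_that("quantify_image errors carry the failing stage", {
  curve <- new_calibration_curve(20, 170, 166.9)
  expect_error(quantify_image("missing.png", curve), "\\[load_image\\]")
  img <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(1, dim = c(32, 32, 3)), img)  # pure white: no spot
  expect_error(quantify_image(img, curve), "\\[roi\\].*no spot detected")
})

test_that("quant_result serializes to JSON and tidies to one row", {
  curve <- fit_calibration(gen_standards(seq(0, 1000, 100),
                                         truth = default_truth, seed = 8))
  img <- withr::local_tempfile(fileext = ".png")
  write_spot_png(gen_spot_image(250, default_truth, seed = 9), img)
  q <- quantify_image(img, curve)
  js <- jsonlite::fromJSON(write_quant_result(q))
  expect_equal(js$ppm, q$ppm)
  expect_equal(js$remark, q$remark)
  expect_equal(
    sort(names(js)),
    sort(c("mean_gray_cmy", "n_pixels_total", "n_outliers_removed", "ppm",
           "half_width", "censored", "remark", "dilution_factor",
           "temperature_c")))
  td <- tidy(q)
  expect_equal(nrow(td), 1L)
  expect_equal(td$ppm, q$ppm)
})
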