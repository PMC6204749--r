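#' Ground-truth bundle for the synthetic-fixture generator
#'
#' Collects the generating parameters every synthetic fixture is drawn from,
#' so that each analysis stage can be tested against known truth. Defaults
#' anchor the printed behaviour of the assay: the calibration curve
#' saturates at 500 ppm (`tau = 500 / ln 20`), colour formation is first
#' order with `K = 0.64` per second toward asymptote `a = 150` gray, and
#' gray drifts linearly from 82 at 25 degC to 96 at 50 degC. Baseline and
#' asymptote gray magnitudes (`G0 = 20`, `Gmax = 170`) are generator
#' choices; published axes do not pin them.
#'
#' @param G0,Gmax,tau Calibration truth (CMY gray baseline, asymptote and
#'   ppm scale constant).
#' @param K,a Kinetics truth: first-order rate constant (1/s) and formation
#'   asymptote (gray).
#' @param temp_anchor_low,temp_anchor_high `(degC, gray)` anchors of the
#'   linear temperature drift.
#' @param pixel_sd Pixel-level gray noise SD in spot images.
#' @param replicate_sd Replicate-level noise SD for calibration standards;
#'   defaults to `pixel_sd / sqrt(1000)`, the standard error of a mean over
#'   roughly a thousand spot pixels.
#' @param series_sd Per-sample noise SD for kinetics and temperature series.
#' @param outlier_fraction,outlier_shift Fraction of spot pixels shifted by
#'   `outlier_shift` CMY gray units (dust/fibre artefacts).
#' @return A `truth_bundle` list.
#' @export
truth_bundle <- function(G0 = 20, Gmax = 170, tau = 500 / log(20),
                         K = 0.64, a = 150,
                         temp_anchor_low = c(25, 82),
                         temp_anchor_high = c(50, 96),
                         pixel_sd = 2,
                         replicate_sd = pixel_sd / sqrt(1000),
                         series_sd = 1,
                         outlier_fraction = 0.02, outlier_shift = 60) {
  structure(
    list(curve = new_calibration_curve(G0 = G0, Gmax = Gmax, tau = tau),
         K = K, a = a,
         temp_anchor_low = temp_anchor_low,
         temp_anchor_high = temp_anchor_high,
         temp_slope = (temp_anchor_high[2] - temp_anchor_low[2]) /
                      (temp_anchor_high[1] - temp_anchor_low[1]),
         pixel_sd = pixel_sd, replicate_sd = replicate_sd,
         series_sd = series_sd,
         outlier_fraction = outlier_fraction,
         outlier_shift = outlier_shift),
    class = "truth_bundle"
  )
}

# truth gray at a temperature: linear through the two anchors
truth_temperature_gray <- function(truth, temperature_c) {
  truth$temp_anchor_low[2] +
    truth$temp_slope * (temperature_c - truth$temp_anchor_low[1])
}

#' Generate a synthetic spot image
#'
#' White background with a centred (or user-placed) circular reagent spot
#' whose interior CMY gray is the truth calibration curve at the requested
#' concentration plus Gaussian pixel noise; a fraction of disc pixels is
#' shifted upward to emulate dust/fibre outliers. Channels are equal
#' (R = G = B = 255 - CMY), clamped to \[0, 255\] and rounded. Output is a
#' pure function of the arguments and `seed`.
#'
#' @param concentration Uric acid concentration, ppm (diluted-sample scale).
#' @param truth A [truth_bundle()].
#' @param size Image side length, pixels.
#' @param spot_radius Disc radius, pixels (`< size / 2`).
#' @param center Disc centre `(row, col)`; default image centre.
#' @param noise_sd Pixel noise SD; defaults to the bundle's `pixel_sd`.
#' @param outlier_fraction Fraction of disc pixels shifted; defaults to the
#'   bundle's.
#' @param seed Integer seed; the global RNG state is left untouched.
#' @return A [pixel_array()].
#' @export
gen_spot_image <- function(concentration, truth = truth_bundle(),
                           size = 200, spot_radius = 60, center = NULL,
                           noise_sd = truth$pixel_sd,
                           outlier_fraction = truth$outlier_fraction,
                           seed = 1) {
  if (concentration < 0) stop("concentration must be >= 0", call. = FALSE)
  if (spot_radius >= size / 2) {
    stop("spot_radius must be smaller than half the image size",
         call. = FALSE)
  }
  if (is.null(center)) center <- c(size / 2 + 0.5, size / 2 + 0.5)
  g_true <- predict_gray(truth$curve, concentration)
  withr::with_seed(seed, {
    rows <- matrix(seq_len(size), size, size)
    cols <- matrix(seq_len(size), size, size, byrow = TRUE)
    inside <- (rows - center[1])^2 + (cols - center[2])^2 <= spot_radius^2
    n_in <- sum(inside)
    cmy <- matrix(0, size, size)  # white background: CMY 0
    spot <- g_true + stats::rnorm(n_in, 0, noise_sd)
    n_out <- round(outlier_fraction * n_in)
    if (n_out > 0) {
      idx <- sample.int(n_in, n_out)
      spot[idx] <- spot[idx] + truth$outlier_shift
    }
    cmy[inside] <- spot
    rgb <- pmin(pmax(round(255 - cmy), 0), 255)
    pixel_array(array(rgb, dim = c(size, size, 3)))
  })
}

#' Write a pixel array to a PNG file
#'
#' @param image A [pixel_array()].
#' @param path Output PNG path.
#' @return `path` invisibly.
#' @export
write_spot_png <- function(image, path) {
  stopifnot(inherits(image, "pixel_array"))
  png::writePNG(unclass(image) / 255, path)
  invisible(path)
}

#' Generate synthetic calibration standards
#'
#' Replicate gray values on the truth curve plus replicate-level Gaussian
#' noise (the noise of a spot-mean, not of single pixels).
#'
#' @param concentrations Concentrations in ppm.
#' @param replicates Replicates per concentration (default 4).
#' @param truth A [truth_bundle()].
#' @param noise_sd Replicate noise SD; defaults to the bundle's
#'   `replicate_sd`.
#' @param seed Integer seed.
#' @return A tibble with columns `concentration_ppm`, `gray` (one row per
#'   replicate), directly consumable by [fit_calibration()].
#' @export
gen_standards <- function(concentrations, replicates = 4,
                          truth = truth_bundle(),
                          noise_sd = truth$replicate_sd, seed = 1) {
  if (any(concentrations < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  withr::with_seed(seed, {
    conc <- rep(concentrations, each = replicates)
    gray <- predict_gray(truth$curve, conc) +
      stats::rnorm(length(conc), 0, noise_sd)
    tibble::tibble(concentration_ppm = conc,
                   gray = pmin(pmax(gray, 0), 255))
  })
}

#' Generate a synthetic colour-formation kinetics series
#'
#' First-order formation `x(t) = a (1 - exp(-K t))` sampled at the video
#' frame rate, plus Gaussian noise, clamped to `[0, a - 0.01]` so the
#' asymptote is never touched.
#'
#' @param truth A [truth_bundle()].
#' @param fps Frames per second.
#' @param duration_s Recording length, seconds.
#' @param noise_sd Per-sample noise SD; defaults to the bundle's
#'   `series_sd`.
#' @param seed Integer seed.
#' @return A kinetics series tibble (`time_s`, `intensity`).
#' @export
gen_kinetics <- function(truth = truth_bundle(), fps = 30, duration_s = 10,
                         noise_sd = truth$series_sd, seed = 1) {
  if (fps <= 0 || duration_s <= 0) {
    stop("fps and duration_s must be positive", call. = FALSE)
  }
  withr::with_seed(seed, {
    t <- (seq_len(round(fps * duration_s)) - 1) / fps
    x <- truth$a * (1 - exp(-truth$K * t)) +
      stats::rnorm(length(t), 0, noise_sd)
    x <- pmin(pmax(x, 0), truth$a - 0.01)
    as_kinetics_series(tibble::tibble(time_s = t, intensity = x))
  })
}

#' Generate a synthetic temperature-drift series
#'
#' Gray values on the line through the truth anchors (82 gray at 25 degC,
#' 96 gray at 50 degC by default) plus Gaussian noise.
#'
#' @param temps Temperatures in degrees C.
#' @param truth A [truth_bundle()].
#' @param noise_sd Per-sample noise SD; defaults to the bundle's
#'   `series_sd`.
#' @param seed Integer seed.
#' @return A tibble with columns `temperature_c`, `gray`, consumable by
#'   [fit_temperature_model()].
#' @export
gen_temperature <- function(temps = seq(25, 50, by = 5),
                            truth = truth_bundle(),
                            noise_sd = truth$series_sd, seed = 1) {
  withr::with_seed(seed, {
    gray <- truth_temperature_gray(truth, temps) +
      stats::rnorm(length(temps), 0, noise_sd)
    tibble::tibble(temperature_c = temps, gray = pmin(pmax(gray, 0), 255))
  })
}

#' Write a fixture set with its manifest
#'
#' Writes the requested fixture (spot PNG, standards CSV, kinetics CSV or
#' temperature CSV) together with a JSON manifest recording the truth
#' parameters and seed, so fixtures are self-describing.
#'
#' @param what One of `"spot"`, `"standards"`, `"kinetics"`,
#'   `"temperature"`.
#' @param dir Output directory (created if needed).
#' @param truth A [truth_bundle()].
#' @param seed Integer seed.
#' @param ... Passed to the corresponding generator (e.g. `concentration`
#'   for spots).
#' @return Invisibly, the paths written.
#' @export
write_fixture_set <- function(what = c("spot", "standards", "kinetics",
                                       "temperature"),
                              dir, truth = truth_bundle(), seed = 1, ...) {
  what <- match.arg(what)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  args <- list(...)
  paths <- character()
  if (what == "spot") {
    conc <- args$concentration %||% 200
    img <- gen_spot_image(conc, truth = truth, seed = seed)
    paths <- file.path(dir, sprintf("spot_%gppm_seed%d.png", conc, seed))
    write_spot_png(img, paths)
  } else if (what == "standards") {
    conc <- args$concentrations %||% seq(0, 1000, by = 50)
    std <- gen_standards(conc, truth = truth, seed = seed)
    paths <- file.path(dir, sprintf("standards_seed%d.csv", seed))
    utils::write.csv(std, paths, row.names = FALSE)
  } else if (what == "kinetics") {
    kin <- gen_kinetics(truth = truth, seed = seed)
    paths <- file.path(dir, sprintf("kinetics_seed%d.csv", seed))
    utils::write.csv(kin, paths, row.names = FALSE)
  } else {
    tmp <- gen_temperature(truth = truth, seed = seed)
    paths <- file.path(dir, sprintf("temperature_seed%d.csv", seed))
    utils::write.csv(tmp, paths, row.names = FALSE)
  }
  manifest <- file.path(dir, sprintf("%s_seed%d_manifest.json", what, seed))
  jsonlite::write_json(
    list(fixture = what, seed = seed, synthetic = TRUE,
         truth = list(G0 = truth$curve$G0, Gmax = truth$curve$Gmax,
                      tau = truth$curve$tau, K = truth$K, a = truth$a,
                      temp_anchor_low = truth$temp_anchor_low,
                      temp_anchor_high = truth$temp_anchor_high,
                      pixel_sd = truth$pixel_sd,
                      replicate_sd = truth$replicate_sd,
                      series_sd = truth$series_sd,
                      outlier_fraction = truth$outlier_fraction,
                      outlier_shift = truth$outlier_shift),
         extra = args),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
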