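#' Remove outlier pixels by Tukey fences
#'
#' Single-pass Tukey rule: values outside
#' \[Q1 - 1.5 IQR, Q3 + 1.5 IQR\] are removed, with quartiles computed by
#' linear interpolation (type 7). The rule is parameter-free and idempotent
#' on its own output, which makes the pixel screening reproducible.
#'
#' @param values Numeric vector of gray values, length >= 5.
#' @return A list with `values` (retained values, original order) and
#'   `n_removed`.
#' @export
eliminate_outliers <- function(values) {
  if (length(values) < 5L) {
    stop("too few pixels for outlier screening", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  keep <- values >= q[1] - 1.5 * iqr & values <= q[2] + 1.5 * iqr
  list(values = values[keep], n_removed = sum(!keep))
}

#' Mean gray value of a pixel set
#'
#' @param values Non-empty numeric vector.
#' @return Arithmetic mean.
#' @export
mean_gray <- function(values) {
  if (length(values) == 0L) stop("no pixels to average", call. = FALSE)
  mean(values)
}

#' Convert a mean gray value to a concentration estimate
#'
#' Applies (optionally) the temperature correction, inverts the calibration
#' curve, scales to the undiluted sample by `dilution_factor`, and attaches a
#' delta-method uncertainty: half-width = z(95%) x residual SD / |dG/dC| at
#' the estimate, on the undiluted scale. Estimates at or beyond 95% of the
#' curve span are censored at the saturation concentration and reported as
#' lower bounds.
#'
#' @param mean_gray Mean CMY gray of the spot.
#' @param curve A `calibration_curve`.
#' @param dilution_factor Ratio of original urine to applied sample
#'   (>= 1, default 2 for a 2X diluted sample).
#' @param temperature_c Measurement temperature, degrees C.
#' @param temp_model Optional `temperature_model`; when supplied and
#'   `temperature_c` differs from the curve's reference temperature the gray
#'   value is corrected before inversion.
#' @return A `concentration_estimate`: list with `ppm`, `half_width`,
#'   `censored`, `dilution_factor`, `temperature_c`.
#' @export
estimate_concentration <- function(mean_gray, curve, dilution_factor = 2,
                                   temperature_c = 25, temp_model = NULL) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (dilution_factor < 1) stop("dilution_factor must be >= 1", call. = FALSE)
  g <- mean_gray
  if (!is.null(temp_model) && temperature_c != curve$temperature_ref) {
    g <- correct_temperature(g, temperature_c, temp_model)
  }
  inv <- invert_calibration(curve, g)
  c_diluted <- inv$ppm
  # dG/dC of the expsat model at the (possibly censored) estimate
  dgdc <- (curve$Gmax - curve$G0) / curve$tau * exp(-c_diluted / curve$tau)
  hw <- stats::qnorm(0.975) * curve$residual_sd / dgdc * dilution_factor
  structure(
    list(ppm = c_diluted * dilution_factor,
         half_width = hw,
         censored = inv$censored,
         dilution_factor = dilution_factor,
         temperature_c = temperature_c),
    class = "concentration_estimate"
  )
}

#' Clinical remark for an estimated urinary uric acid concentration
#'
#' The published acceptable range for urinary uric acid is 300-700 ppm
#' (inclusive at both boundaries).
#'
#' @param ppm Estimated concentration, ppm (undiluted scale); censored
#'   estimates use their lower bound.
#' @return One of `"below_range"`, `"within_acceptable_limit"`,
#'   `"above_acceptable_limit"`.
#' @export
make_remark <- function(ppm) {
  if (any(ppm < 0)) stop("concentration must be non-negative", call. = FALSE)
  ifelse(ppm < 300, "below_range",
         ifelse(ppm <= 700, "within_acceptable_limit",
                "above_acceptable_limit"))
}

#' Quantify uric acid from a spot image
#'
#' Full readout pipeline: load image, convert to RGB gray then CMY gray,
#' detect or apply the ROI, screen outlier pixels, average, invert the
#' calibration curve (with optional temperature correction), scale by the
#' dilution factor and attach the clinical remark.
#'
#' @param path Path to the spot image (PNG/JPEG/TIFF).
#' @param curve A `calibration_curve`.
#' @param roi A [roi_spec()] or a string `"auto"`, `"full"`,
#'   `"circle:row,col,radius"`.
#' @param dilution_factor Dilution of the applied sample (default 2).
#' @param temperature_c Measurement temperature, degrees C (default 25).
#' @param temp_model Optional `temperature_model`.
#' @param verbose Emit per-stage progress messages.
#' @return A `quant_result`: list with `mean_gray_cmy`, `n_pixels_total`,
#'   `n_outliers_removed`, `ppm`, `half_width`, `censored`, `remark`,
#'   `dilution_factor`, `temperature_c`.
#' @examples
#' \donttest{
#' truth <- truth_bundle()
#' img <- tempfile(fileext = ".png")
#' write_spot_png(gen_spot_image(200, truth, seed = 1), img)
#' curve <- fit_calibration(gen_standards(seq(0, 1000, 100), truth = truth,
#'                                        seed = 1))
#' quantify_image(img, curve)
#' }
#' @export
quantify_image <- function(path, curve, roi = "auto", dilution_factor = 2,
                           temperature_c = 25, temp_model = NULL,
                           verbose = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  say <- function(...) if (verbose) message(sprintf(...))

  img <- stage("load_image", load_image(path))
  say("load_image: %d x %d px", dim(img)[1], dim(img)[2])
  cmy <- stage("to_cmy", to_cmy(rgb_to_gray(img)))
  roi <- stage("roi", {
    r <- parse_roi(roi)
    if (r$mode == "auto" && is.null(r$center)) detect_spot_roi(cmy) else r
  })
  say("roi: %s", format(roi))
  vals <- stage("extract_roi", extract_roi(cmy, roi))
  filt <- stage("eliminate_outliers", eliminate_outliers(as.numeric(vals)))
  say("outliers: removed %d of %d px", filt$n_removed, length(vals))
  mg <- stage("mean_gray", mean_gray(filt$values))
  est <- stage("estimate_concentration",
               estimate_concentration(mg, curve,
                                      dilution_factor = dilution_factor,
                                      temperature_c = temperature_c,
                                      temp_model = temp_model))
  remark <- stage("make_remark", make_remark(est$ppm))
  say("estimate: %.1f ppm (%s)", est$ppm, remark)
  structure(
    list(mean_gray_cmy = mg,
         n_pixels_total = length(vals),
         n_outliers_removed = filt$n_removed,
         ppm = est$ppm,
         half_width = est$half_width,
         censored = est$censored,
         remark = remark,
         dilution_factor = dilution_factor,
         temperature_c = temperature_c),
    class = "quant_result"
  )
}

#' @export
print.quant_result <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.quant_result <- function(x, ...) {
  sprintf(
    "uric acid %s%.0f +/- %.0f ppm (%s; mean CMY gray %.2f over %d px, %d outliers removed, %gX dilution, %.0f degC)",
    if (x$censored == "above_saturation") ">= " else "",
    x$ppm, x$half_width, gsub("_", " ", x$remark), x$mean_gray_cmy,
    x$n_pixels_total, x$n_outliers_removed, x$dilution_factor,
    x$temperature_c)
}

#' Serialize a quantification result to JSON
#'
#' @param result A `quant_result`.
#' @param path Output path; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
write_quant_result <- function(result, path = NULL) {
  stopifnot(inherits(result, "quant_result"))
  if (is.null(path)) {
    return(jsonlite::toJSON(unclass(result), auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
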