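#' Saturating concentration-gray calibration model
#'
#' The calibration curve relates uric acid concentration `C` (ppm, on the
#' diluted-sample scale) to CMY gray intensity by exponential saturation:
#' \deqn{G(C) = G_0 + (G_{max} - G_0)\,(1 - e^{-C/\tau})}
#' `G0` is the blank (0 ppm) gray, `Gmax` the asymptotic gray, and `tau` the
#' concentration scale constant. The operational saturation concentration
#' `C_sat95 = tau * ln(20)` is where the curve reaches 95% of its span; above
#' it the colour signal no longer discriminates and estimates are censored.
#'
#' @param curve A `calibration_curve` fitted by [fit_calibration()] or built
#'   by [new_calibration_curve()].
#' @param concentration Concentration(s) in ppm, `>= 0`.
#' @return Predicted gray value(s) in CMY units.
#' @export
predict_gray <- function(curve, concentration) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(concentration < 0)) {
    stop("concentration must be non-negative", call. = FALSE)
  }
  curve$G0 + (curve$Gmax - curve$G0) * (1 - exp(-concentration / curve$tau))
}

#' Construct a calibration curve from known parameters
#'
#' Used by the synthetic generator (truth curves) and when loading a saved
#' calibration from JSON; [fit_calibration()] is the estimation route.
#'
#' @param G0 Baseline gray at 0 ppm.
#' @param Gmax Asymptotic gray, `> G0`.
#' @param tau Concentration scale constant in ppm, `> 0`.
#' @param r_squared,residual_sd,n_standards Fit diagnostics (optional for
#'   truth curves).
#' @param temperature_ref Reference temperature in degrees C (default 25,
#'   room temperature at which calibration standards are scanned).
#' @return A `calibration_curve` object.
#' @export
new_calibration_curve <- function(G0, Gmax, tau, r_squared = NA_real_,
                                  residual_sd = 0, n_standards = NA_integer_,
                                  temperature_ref = 25) {
  if (Gmax <= G0) stop("Gmax must exceed G0", call. = FALSE)
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  structure(
    list(model_id = "expsat", G0 = G0, Gmax = Gmax, tau = tau,
         C_sat95 = tau * log(20), r_squared = r_squared,
         residual_sd = residual_sd, n_standards = n_standards,
         temperature_ref = temperature_ref),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve [expsat]>\n")
  cat(sprintf("  G0 = %.3f, Gmax = %.3f, tau = %.3f ppm\n",
              x$G0, x$Gmax, x$tau))
  cat(sprintf("  C_sat95 = %.1f ppm, r^2 = %s, residual SD = %.3f gray\n",
              x$C_sat95,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
              x$residual_sd))
  cat(sprintf("  fitted on %s standards at %.0f degC\n",
              ifelse(is.na(x$n_standards), "?", x$n_standards),
              x$temperature_ref))
  invisible(x)
}

#' Fit the saturating calibration curve to standards
#'
#' Nonlinear least squares of the exponential-saturation model on all
#' replicate points. Initialisation: `G0` = mean gray at the lowest
#' concentration, `Gmax` = largest per-concentration mean, `tau` = half the
#' largest concentration; Levenberg-Marquardt with parameter tolerance 1e-8.
#'
#' @param standards A data frame with columns `concentration_ppm` and `gray`
#'   (one row per replicate measurement). At least 4 distinct concentrations
#'   are required, including one at or below 50 ppm and one at or above
#'   400 ppm, so that both the baseline and the saturation region are
#'   anchored.
#' @param temperature_ref Reference temperature of the standards, degrees C.
#' @return A `calibration_curve` with fit diagnostics (`r_squared` over all
#'   replicate points and `residual_sd` with 3 fitted parameters).
#' @export
fit_calibration <- function(standards, temperature_ref = 25) {
  standards <- as.data.frame(standards)
  req <- c("concentration_ppm", "gray")
  if (!all(req %in% names(standards))) {
    stop("standards need columns concentration_ppm and gray", call. = FALSE)
  }
  conc <- standards$concentration_ppm
  gray <- standards$gray
  u <- sort(unique(conc))
  if (length(u) < 4L || min(u) > 50 || max(u) < 400) {
    stop(paste("need >= 4 distinct concentrations spanning <= 50 ppm",
               "to >= 400 ppm"), call. = FALSE)
  }
  means <- vapply(u, function(cc) mean(gray[conc == cc]), numeric(1))

  # the model is monotone increasing; standards decreasing over the lower
  # half of the range cannot be fitted meaningfully
  lower <- u <= (min(u) + max(u)) / 2
  if (sum(lower) >= 2L &&
      stats::coef(stats::lm(means[lower] ~ u[lower]))[2] < 0) {
    stop("non-monotone standards", call. = FALSE)
  }

  start <- list(G0 = means[1], Gmax = max(means), tau = max(u) / 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      gray ~ G0 + (Gmax - G0) * (1 - exp(-conc / tau)),
      data = data.frame(conc = conc, gray = gray),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-8)
    ),
    error = function(e) {
      stop(sprintf("calibration fit did not converge: %s",
                   conditionMessage(e)), call. = FALSE)
    }
  )
  p <- stats::coef(fit)
  if (p["Gmax"] <= p["G0"] || p["tau"] <= 0) {
    stop("calibration fit degenerate: requires Gmax > G0 and tau > 0",
         call. = FALSE)
  }
  res <- stats::resid(fit)
  ss_res <- sum(res^2)
  ss_tot <- sum((gray - mean(gray))^2)
  curve <- new_calibration_curve(
    G0 = unname(p["G0"]), Gmax = unname(p["Gmax"]), tau = unname(p["tau"]),
    r_squared = 1 - ss_res / ss_tot,
    residual_sd = sqrt(ss_res / max(length(gray) - 3L, 1L)),
    n_standards = length(u),
    temperature_ref = temperature_ref
  )
  curve$data <- tibble::tibble(concentration_ppm = conc, gray = gray)
  curve
}

#' Invert the calibration curve
#'
#' Maps a CMY gray value back to concentration. Grays at or above 95% of the
#' fitted span are censored at the saturation concentration `C_sat95` (the
#' returned value is then a lower bound). Grays slightly below the baseline
#' (within two residual SDs) clamp to 0 ppm; anything lower is flagged as
#' signal below blank.
#'
#' @param curve A `calibration_curve`.
#' @param gray CMY gray value (scalar).
#' @return A list with `ppm` (diluted-sample scale) and `censored`
#'   (`"none"` or `"above_saturation"`).
#' @export
invert_calibration <- function(curve, gray) {
  stopifnot(inherits(curve, "calibration_curve"), length(gray) == 1L)
  span <- curve$Gmax - curve$G0
  if (gray <= curve$G0 - 2 * curve$residual_sd && gray < curve$G0) {
    stop("signal below blank", call. = FALSE)
  }
  if (gray >= curve$G0 + 0.95 * span) {
    return(list(ppm = curve$C_sat95, censored = "above_saturation"))
  }
  if (gray < curve$G0) {
    return(list(ppm = 0, censored = "none"))
  }
  list(ppm = -curve$tau * log(1 - (gray - curve$G0) / span),
       censored = "none")
}

#' Fit the linear temperature-drift model
#'
#' Gray intensity of the developed colour drifts linearly upward with
#' temperature (paper yellowing at higher temperature contributes); an
#' ordinary least-squares line `gray = intercept + slope * T` captures the
#' drift so measurements can be referred back to the calibration temperature.
#'
#' @param pairs A data frame with columns `temperature_c` and `gray`,
#'   covering at least 3 distinct temperatures.
#' @param reference_temp Reference temperature in degrees C (default 25);
#'   must lie within the fitted temperature range.
#' @return A `temperature_model` with `slope` (gray per degC), `intercept`,
#'   `reference_temp` and `r_squared`.
#' @export
fit_temperature_model <- function(pairs, reference_temp = 25) {
  pairs <- as.data.frame(pairs)
  if (!all(c("temperature_c", "gray") %in% names(pairs))) {
    stop("pairs need columns temperature_c and gray", call. = FALSE)
  }
  if (length(unique(pairs$temperature_c)) < 3L) {
    stop("need >= 3 distinct temperatures", call. = FALSE)
  }
  if (reference_temp < min(pairs$temperature_c) ||
      reference_temp > max(pairs$temperature_c)) {
    stop("reference_temp must lie within the fitted temperature range",
         call. = FALSE)
  }
  fit <- stats::lm(gray ~ temperature_c, data = pairs)
  ss_tot <- sum((pairs$gray - mean(pairs$gray))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::resid(fit)^2) / ss_tot
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         reference_temp = reference_temp,
         r_squared = r2),
    class = "temperature_model"
  )
}

#' @export
print.temperature_model <- function(x, ...) {
  cat(sprintf(
    "<temperature_model: gray = %.3f %+.4f * T degC, ref %.0f degC, r^2 %.4f>\n",
    x$intercept, x$slope, x$reference_temp, x$r_squared))
  invisible(x)
}

#' Refer a gray value to the reference temperature
#'
#' Subtracts the linear drift: `gray - slope * (T - reference_temp)`,
#' clamped to \[0, 255\] (with a warning if clamping occurs).
#'
#' @param gray Gray value(s).
#' @param temperature_c Temperature of the measurement, degrees C.
#' @param model A `temperature_model` from [fit_temperature_model()].
#' @return Corrected gray value(s).
#' @export
correct_temperature <- function(gray, temperature_c, model) {
  stopifnot(inherits(model, "temperature_model"))
  out <- gray - model$slope * (temperature_c - model$reference_temp)
  if (any(out < 0) || any(out > 255)) {
    warning("temperature-corrected gray clamped to [0, 255]", call. = FALSE)
    out <- pmin(pmax(out, 0), 255)
  }
  out
}

#' Read and write calibration objects as JSON
#'
#' @param curve A `calibration_curve`.
#' @param model A `temperature_model`.
#' @param path Output / input JSON path.
#' @return `write_*` return `path` invisibly; `read_*` return the object.
#' @name calibration_io
NULL

#' @rdname calibration_io
#' @export
write_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  keep <- c("model_id", "G0", "Gmax", "tau", "C_sat95", "r_squared",
            "residual_sd", "n_standards", "temperature_ref")
  jsonlite::write_json(curve[keep], path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname calibration_io
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$model_id, "expsat")) {
    stop(sprintf("unsupported calibration model '%s'", x$model_id),
         call. = FALSE)
  }
  new_calibration_curve(
    G0 = x$G0, Gmax = x$Gmax, tau = x$tau,
    r_squared = if (is.null(x$r_squared)) NA_real_ else x$r_squared,
    residual_sd = x$residual_sd,
    n_standards = if (is.null(x$n_standards)) NA_integer_ else x$n_standards,
    temperature_ref = x$temperature_ref
  )
}

#' @rdname calibration_io
#' @export
write_temperature_model <- function(model, path) {
  stopifnot(inherits(model, "temperature_model"))
  jsonlite::write_json(
    model[c("slope", "intercept", "reference_temp", "r_squared")],
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname calibration_io
#' @export
read_temperature_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x[c("slope", "intercept", "reference_temp", "r_squared")],
            class = "temperature_model")
}
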