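#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for fitted calibration curves
#'
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter (`term`, `estimate`);
#'   `glance()`: a one-row tibble of fit diagnostics.
#' @export
tidy.calibration_curve <- function(x, ...) {
  tibble::tibble(term = c("G0", "Gmax", "tau"),
                 estimate = c(x$G0, x$Gmax, x$tau))
}

#' @rdname tidy.calibration_curve
#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(C_sat95 = x$C_sat95, r_squared = x$r_squared,
                 residual_sd = x$residual_sd, n_standards = x$n_standards,
                 temperature_ref = x$temperature_ref)
}

#' Tidiers for temperature-drift models
#'
#' @param x A `temperature_model`.
#' @param ... Unused.
#' @return `tidy()`: `term`/`estimate` rows; `glance()`: one-row summary.
#' @export
tidy.temperature_model <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.temperature_model
#' @export
glance.temperature_model <- function(x, ...) {
  tibble::tibble(slope = x$slope, reference_temp = x$reference_temp,
                 r_squared = x$r_squared)
}

#' Tidiers for kinetics results
#'
#' @param x A `kinetics_result`.
#' @param ... Unused.
#' @return `tidy()`: the per-order fit table; `glance()`: the selected
#'   order and its rate constant.
#' @export
tidy.kinetics_result <- function(x, ...) x$fits

#' @rdname tidy.kinetics_result
#' @export
glance.kinetics_result <- function(x, ...) {
  tibble::tibble(best_order = x$best_order, K_best = x$K_best,
                 a_best = x$a_best,
                 r_squared = x$fits$r_squared[x$best_order + 1L])
}

#' Tidier for quantification results
#'
#' @param x A `quant_result`.
#' @param ... Unused.
#' @return A one-row tibble with the full readout record.
#' @export
tidy.quant_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Plot a calibration curve with its standards
#'
#' @param object A `calibration_curve` from [fit_calibration()].
#' @param ... Unused.
#' @return A ggplot: replicate points, fitted curve, and the saturation
#'   concentration `C_sat95` as a dashed vertical line.
#' @export
autoplot.calibration_curve <- function(object, ...) {
  upper <- if (!is.null(object$data)) {
    max(object$data$concentration_ppm)
  } else {
    2 * object$C_sat95
  }
  grid <- tibble::tibble(concentration_ppm = seq(0, upper, length.out = 200))
  grid$gray <- predict_gray(object, grid$concentration_ppm)
  p <- ggplot2::ggplot(grid,
                       ggplot2::aes(.data$concentration_ppm, .data$gray)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$C_sat95, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "uric acid (ppm, diluted sample)",
                  y = "CMY gray value",
                  title = "Saturating calibration curve",
                  subtitle = sprintf("C_sat95 = %.0f ppm", object$C_sat95))
  if (!is.null(object$data)) {
    p <- p + ggplot2::geom_point(data = object$data, alpha = 0.6)
  }
  p
}

#' Plot the linearized kinetics fits
#'
#' @param object A `kinetics_result` from [analyze_kinetics()].
#' @param series The kinetics series the result was fitted to.
#' @param ... Unused.
#' @return A ggplot of the three linearizations with their least-squares
#'   lines, the selected order highlighted in the panel labels.
#' @export
autoplot.kinetics_result <- function(object, series, ...) {
  series <- as_kinetics_series(series)
  keep <- formation_phase(series)
  sub <- series[keep, ]
  panels <- dplyr::bind_rows(purrr::map(seq_len(nrow(object$fits)),
                                        function(i) {
    f <- object$fits[i, ]
    lin <- linearize(sub, order = f$order,
                     a = if (f$order == 0) NULL else f$a_used)
    lin$order <- sprintf("order %d (r² = %.3f)%s", f$order,
                         f$r_squared,
                         if (f$order == object$best_order) " *" else "")
    lin
  }))
  ggplot2::ggplot(panels, ggplot2::aes(.data$time_s, .data$y)) +
    ggplot2::geom_point(alpha = 0.35, size = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.5) +
    ggplot2::facet_wrap(~order, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "linearized intensity",
                  title = "Reaction-order linearizations",
                  subtitle = sprintf("selected order %d, K = %.3g",
                                     object$best_order, object$K_best))
}

#' Plot a temperature-drift model
#'
#' @param object A `temperature_model`.
#' @param pairs Optional data frame (`temperature_c`, `gray`) of the fitted
#'   observations.
#' @param ... Unused.
#' @return A ggplot of the fitted drift line.
#' @export
autoplot.temperature_model <- function(object, pairs = NULL, ...) {
  rng <- if (!is.null(pairs)) range(pairs$temperature_c) else c(25, 50)
  grid <- tibble::tibble(temperature_c = seq(rng[1], rng[2],
                                             length.out = 50))
  grid$gray <- object$intercept + object$slope * grid$temperature_c
  p <- ggplot2::ggplot(grid, ggplot2::aes(.data$temperature_c, .data$gray)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "temperature (degC)", y = "gray value",
                  title = "Linear temperature drift",
                  subtitle = sprintf("%.3f gray / degC", object$slope))
  if (!is.null(pairs)) p <- p + ggplot2::geom_point(data = pairs)
  p
}
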