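#' Kinetics series construction
#'
#' A kinetics series records Prussian-blue colour formation `x(t)` (CMY gray,
#' a proxy for product amount) at strictly increasing times starting at 0.
#' `frames_to_series` converts per-frame mean spot grays from a video
#' (default 30 frames per second) into such a series. Frames with missing
#' gray values (failed extraction) are dropped with a warning rather than
#' interpolated.
#'
#' @param frame_grays Numeric vector of mean spot gray per video frame.
#' @param fps Frame rate, frames per second (> 0).
#' @return A tibble with columns `time_s` and `intensity` (a
#'   `kinetics_series`).
#' @export
frames_to_series <- function(frame_grays, fps = 30) {
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  times <- (seq_along(frame_grays) - 1) / fps
  drop <- !is.finite(frame_grays)
  if (any(drop)) {
    warning(sprintf("dropping %d frame(s) with missing gray values",
                    sum(drop)), call. = FALSE)
    times <- times[!drop]
    frame_grays <- frame_grays[!drop]
  }
  as_kinetics_series(tibble::tibble(time_s = times, intensity = frame_grays))
}

#' @rdname frames_to_series
#' @param series A data frame with columns `time_s` (strictly increasing,
#'   starting at 0) and `intensity` (gray values in \[0, 255\]), at least 10
#'   samples.
#' @export
as_kinetics_series <- function(series) {
  series <- tibble::as_tibble(series)
  if (!all(c("time_s", "intensity") %in% names(series))) {
    stop("kinetics series needs columns time_s and intensity", call. = FALSE)
  }
  if (nrow(series) < 10L) {
    stop("kinetics series needs >= 10 samples", call. = FALSE)
  }
  if (any(diff(series$time_s) <= 0) || series$time_s[1] < 0) {
    stop("time_s must be strictly increasing and non-negative",
         call. = FALSE)
  }
  if (any(series$intensity < 0) || any(series$intensity > 255)) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  class(series) <- c("kinetics_series", class(series))
  series
}

# formation-phase subset used for the linearized fits: once the signal
# plateaus, a - x is noise-dominated and its log/reciprocal transforms are
# uninformative, so points with x > 0.95 * max(x) are excluded (all orders
# use the same subset so r^2 values are comparable)
formation_phase <- function(series) {
  keep <- series$intensity <= 0.95 * max(series$intensity)
  if (sum(keep) < 10L) keep <- rep(TRUE, nrow(series))
  keep
}

#' Estimate the colour-formation asymptote
#'
#' The asymptote `a` (limiting gray at reaction completion, a proxy for the
#' initial reactant amount) is estimated by nonlinear least squares of the
#' integrated rate law of the requested order: `x = a (1 - exp(-K t))` for
#' first order, `x = a - 1/(K t + 1/a)` for second order. If the nonlinear
#' fit fails, a grid search over `a` in `(max(x), 1.5 max(x)]` (200 steps)
#' maximizing the linearized fit's r-squared is used, ties broken toward
#' smaller `a`.
#'
#' @param series A kinetics series (see [as_kinetics_series()]).
#' @param order Reaction order whose rate law defines the asymptote (1 or 2).
#' @return Estimated asymptote `a` in gray units (`a > 0`).
#' @export
estimate_asymptote <- function(series, order = 1) {
  series <- as_kinetics_series(series)
  x <- series$intensity
  t <- series$time_s
  m <- max(x)
  if (m <= 0) stop("no product formation", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("degenerate series: intensity constant from t = 0", call. = FALSE)
  }
  t_half <- t[which.min(abs(x - m / 2))]
  k0 <- log(2) / max(t_half, t[2])
  a <- tryCatch({
    fit <- if (order == 1) {
      minpack.lm::nlsLM(x ~ a * (1 - exp(-K * t)),
                        data = data.frame(t = t, x = x),
                        start = list(a = 1.05 * m, K = k0),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-15, ptol = 1e-15))
    } else {
      minpack.lm::nlsLM(x ~ a - 1 / (K * t + 1 / a),
                        data = data.frame(t = t, x = x),
                        start = list(a = 1.05 * m, K = k0 / m),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-15, ptol = 1e-15))
    }
    ca <- unname(stats::coef(fit)["a"])
    if (!is.finite(ca) || ca <= 0) stop("invalid asymptote")
    ca
  }, error = function(e) NA_real_)
  if (is.na(a)) a <- asymptote_grid(series, order)
  a
}

# fallback: coarse grid over (max(x), 1.5 max(x)] maximizing linearized r^2
asymptote_grid <- function(series, order) {
  m <- max(series$intensity)
  grid <- m + seq_len(200) * (0.5 * m) / 200
  r2 <- vapply(grid, function(a) {
    f <- try(fit_order(series, order = order, a = a), silent = TRUE)
    if (inherits(f, "try-error")) -Inf else f$r_squared
  }, numeric(1))
  grid[which.max(r2)]
}

#' Linearize a kinetics series under a candidate reaction order
#'
#' Integrated rate laws plotted as straight lines: order 0, `y = x`;
#' order 1, `y = log10(a - x)` (so `ln(10) * log10(a - x) = -K t + c`);
#' order 2, `y = 1/(a - x)`. Points with `a - x <= 0` are excluded (they can
#' only arise when `a` falls below an observed intensity).
#'
#' @param series A kinetics series.
#' @param order Candidate order, 0, 1 or 2.
#' @param a Asymptote gray; required (and `> 0`) for orders 1 and 2.
#' @return A tibble with columns `time_s` and `y` (transformed intensity).
#' @export
linearize <- function(series, order, a = NULL) {
  series <- as_kinetics_series(series)
  order <- match_order(order)
  x <- series$intensity
  if (order == 0L) {
    return(tibble::tibble(time_s = series$time_s, y = x))
  }
  if (is.null(a)) stop("orders 1 and 2 require an asymptote a", call. = FALSE)
  z <- a - x
  ok <- z > 0
  if (!any(ok)) {
    stop("asymptote a must exceed observed intensities", call. = FALSE)
  }
  y <- if (order == 1L) log10(z[ok]) else 1 / z[ok]
  tibble::tibble(time_s = series$time_s[ok], y = y)
}

match_order <- function(order) {
  if (!order %in% c(0, 1, 2)) stop("order must be 0, 1 or 2", call. = FALSE)
  as.integer(order)
}

#' Fit one candidate reaction order
#'
#' Ordinary least squares of the linearized series on time, restricted to
#' the formation phase (intensities at or below 95% of the observed
#' maximum). The rate constant is recovered from the slope: order 0,
#' `K = slope` (gray/s); order 1, `K = -ln(10) * slope` (1/s, since the
#' fitted axis is log10); order 2, `K = slope` (1/(gray s)).
#'
#' @param series A kinetics series.
#' @param order Candidate order, 0, 1 or 2.
#' @param a Asymptote gray (orders 1 and 2).
#' @return An `order_fit`: list with `order`, `a_used`, `slope`,
#'   `intercept`, `r_squared`, `K`, `n_used`.
#' @export
fit_order <- function(series, order, a = NULL) {
  series <- as_kinetics_series(series)
  order <- match_order(order)
  keep <- formation_phase(series)
  sub <- series[keep, ]
  lin <- linearize(sub, order = order, a = a)
  if (nrow(lin) < 10L) {
    stop("too few usable points for linearized fit", call. = FALSE)
  }
  if (stats::sd(lin$time_s) == 0) {
    stop("degenerate series: no time variance", call. = FALSE)
  }
  fit <- stats::lm(y ~ time_s, data = lin)
  slope <- unname(stats::coef(fit)[2])
  K <- switch(as.character(order),
              "0" = slope, "1" = -log(10) * slope, "2" = slope)
  ss_tot <- sum((lin$y - mean(lin$y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::resid(fit)^2) / ss_tot
  structure(
    list(order = order, a_used = if (order == 0L) NA_real_ else a,
         slope = slope, intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, K = K, n_used = nrow(lin)),
    class = "order_fit"
  )
}

#' @export
print.order_fit <- function(x, ...) {
  unit <- switch(as.character(x$order),
                 "0" = "gray/s", "1" = "1/s", "2" = "1/(gray s)")
  cat(sprintf("<order_fit: order %d, K = %.4g %s, r^2 = %.4f, n = %d>\n",
              x$order, x$K, unit, x$r_squared, x$n_used))
  invisible(x)
}

#' Select the reaction order and rate constant of colour formation
#'
#' Estimates the asymptote per candidate order (first- and second-order rate
#' laws have their own `a`), fits all three linearizations, and selects the
#' best order by r-squared with a parsimony tie-break: the lowest order
#' whose r-squared is within `tie_margin` of the maximum wins. The margin
#' guards the zero-order model, which the higher orders can imitate
#' arbitrarily well by letting `a` grow large.
#'
#' @param series A kinetics series (data frame with `time_s`, `intensity`).
#' @param tie_margin r-squared margin within which a lower order is
#'   preferred (default 1e-3).
#' @return A `kinetics_result`: list with `fits` (per-order tibble),
#'   `best_order`, `K_best`, `a_best`.
#' @examples
#' series <- gen_kinetics(truth_bundle(), seed = 1)
#' analyze_kinetics(series)
#' @export
analyze_kinetics <- function(series, tie_margin = 1e-3) {
  series <- as_kinetics_series(series)
  a1 <- estimate_asymptote(series, order = 1)
  a2 <- estimate_asymptote(series, order = 2)
  fits <- list(fit_order(series, 0),
               fit_order(series, 1, a = a1),
               fit_order(series, 2, a = a2))
  r2 <- vapply(fits, `[[`, numeric(1), "r_squared")
  best <- min(which(r2 >= max(r2) - tie_margin)) - 1L
  structure(
    list(fits = dplyr::bind_rows(purrr::map(fits,
                                            ~ tibble::as_tibble(unclass(.x)))),
         best_order = best,
         K_best = fits[[best + 1L]]$K,
         a_best = fits[[best + 1L]]$a_used),
    class = "kinetics_result"
  )
}

#' @export
print.kinetics_result <- function(x, ...) {
  unit <- switch(as.character(x$best_order),
                 "0" = "gray/s", "1" = "1/s", "2" = "1/(gray s)")
  cat(sprintf("<kinetics_result: best order %d, K = %.4g %s>\n",
              x$best_order, x$K_best, unit))
  print(x$fits)
  invisible(x)
}

#' Read a kinetics CSV
#'
#' Accepts either columns `time_s, intensity` or `frame_index, intensity`
#' (converted through [frames_to_series()] with the supplied `fps`).
#'
#' @param path CSV path.
#' @param fps Frame rate used when the file carries frame indices.
#' @return A kinetics series tibble.
#' @export
read_kinetics_csv <- function(path, fps = 30) {
  df <- utils::read.csv(path)
  if (all(c("time_s", "intensity") %in% names(df))) {
    return(as_kinetics_series(df))
  }
  if (all(c("frame_index", "intensity") %in% names(df))) {
    return(frames_to_series(df$intensity[order(df$frame_index)], fps = fps))
  }
  stop("kinetics CSV needs columns time_s,intensity or frame_index,intensity",
       call. = FALSE)
}

#' Serialize a kinetics result to JSON
#'
#' @param result A `kinetics_result`.
#' @param path Output path; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_kinetics_result <- function(result, path = NULL) {
  stopifnot(inherits(result, "kinetics_result"))
  payload <- list(fits = result$fits, best_order = result$best_order,
                  K_best = result$K_best, a_best = result$a_best)
  if (is.null(path)) {
    return(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                            na = "null"))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
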