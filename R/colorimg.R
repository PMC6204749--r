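#' Pixel arrays and gray matrices
#'
#' A `pixel_array` is an H x W x 3 integer array of 8-bit RGB intensities
#' (0-255). A `gray_matrix` is an H x W numeric matrix of gray intensities in
#' \[0, 255\] tagged with a colour `scheme`: `"rgb_gray"` (0 = black, 255 =
#' white) or `"cmy_gray"` (255 = black; the darker the spot, the higher the
#' value, and the higher the analyte concentration). Gray values are kept as
#' exact fractions after channel averaging; rounding to integers happens only
#' on display or when an image is written to disk.
#'
#' @param x For `pixel_array()`, an H x W x 3 numeric array with values in
#'   \[0, 255\]; for `gray_matrix()`, a numeric matrix with values in
#'   \[0, 255\].
#' @param scheme Colour scheme tag, `"rgb_gray"` or `"cmy_gray"`.
#' @return An object of class `pixel_array` or `gray_matrix`.
#' @examples
#' px <- pixel_array(array(255L, dim = c(4, 4, 3)))
#' g  <- rgb_to_gray(px)
#' range(g)
#' @name pixel_array
NULL

#' @rdname pixel_array
#' @export
pixel_array <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L) {
    stop("pixel_array requires an H x W x 3 array", call. = FALSE)
  }
  if (anyNA(x) || any(x < 0) || any(x > 255)) {
    stop("channel values must lie in [0, 255]", call. = FALSE)
  }
  if (any(x != round(x))) {
    stop("channel values must be integers (8-bit contract)", call. = FALSE)
  }
  storage.mode(x) <- "integer"
  structure(x, class = "pixel_array")
}

#' @rdname pixel_array
#' @export
gray_matrix <- function(x, scheme = c("rgb_gray", "cmy_gray")) {
  scheme <- match.arg(scheme)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("gray_matrix requires a numeric matrix", call. = FALSE)
  }
  if (anyNA(x) || any(x < 0) || any(x > 255)) {
    stop("gray values must lie in [0, 255]", call. = FALSE)
  }
  structure(x, scheme = scheme, class = "gray_matrix")
}

#' @export
print.pixel_array <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<pixel_array: %d x %d px, 3 channels, 8-bit>\n", d[1], d[2]))
  invisible(x)
}

#' @export
print.gray_matrix <- function(x, ...) {
  cat(sprintf("<gray_matrix [%s]: %d x %d px, range %.1f-%.1f>\n",
              attr(x, "scheme"), nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Scheme tag of a gray matrix
#' @param gray A `gray_matrix`.
#' @return `"rgb_gray"` or `"cmy_gray"`.
#' @export
gray_scheme <- function(gray) {
  stopifnot(inherits(gray, "gray_matrix"))
  attr(gray, "scheme")
}

#' Load an 8-bit RGB image of a reagent spot
#'
#' Reads a PNG, JPEG or TIFF raster into a [pixel_array()]. Grayscale files
#' are promoted to three identical channels and alpha channels are dropped.
#' 16-bit rasters are rescaled to the 8-bit contract by integer division by
#' 257 (65535 / 255).
#'
#' @param path Path to a PNG, JPEG or TIFF file.
#' @return A [pixel_array()] with the original pixel dimensions.
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop(sprintf("cannot read image file '%s'", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
      png  = round(png::readPNG(path) * 65535) %/% 257,
      jpg  = ,
      jpeg = round(jpeg::readJPEG(path) * 255),
      tif  = ,
      tiff = {
        v <- tiff::readTIFF(path, as.is = TRUE)
        if (any(v != round(v))) round(v * 65535) %/% 257  # normalized floats
        else if (max(v) > 255) v %/% 257L
        else v
      },
      stop(sprintf("unsupported image format '%s' for '%s'", ext, path),
           call. = FALSE)
    ),
    error = function(e) {
      stop(sprintf("cannot decode image file '%s': %s", path,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  if (is.matrix(raw)) raw <- array(raw, dim = c(dim(raw), 1L))
  nch <- dim(raw)[3]
  rgb <- if (nch >= 3L) raw[, , 1:3, drop = FALSE]
         else array(raw[, , 1L], dim = c(dim(raw)[1:2], 3L))
  if (any(dim(rgb)[1:2] < 16L)) {
    stop("image too small for ROI analysis", call. = FALSE)
  }
  pixel_array(rgb)
}

#' Convert an RGB image to mean-channel gray
#'
#' Per pixel, gray = (red + green + blue) / 3, kept as an exact fraction.
#'
#' @param image A [pixel_array()].
#' @return A [gray_matrix()] with scheme `"rgb_gray"`.
#' @export
rgb_to_gray <- function(image) {
  stopifnot(inherits(image, "pixel_array"))
  g <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  gray_matrix(matrix(g, nrow = dim(image)[1]), scheme = "rgb_gray")
}

#' Convert RGB gray to CMY gray
#'
#' CMY = 255 - RGB, so that darker colour (more Prussian blue, more uric
#' acid) maps to a higher value. Applying the conversion twice is an error:
#' the scheme tag guards against accidental double inversion.
#'
#' @param gray A [gray_matrix()] with scheme `"rgb_gray"`.
#' @return A [gray_matrix()] with scheme `"cmy_gray"`.
#' @export
to_cmy <- function(gray) {
  stopifnot(inherits(gray, "gray_matrix"))
  if (gray_scheme(gray) == "cmy_gray") {
    stop("double conversion: matrix is already in cmy_gray scheme",
         call. = FALSE)
  }
  gray_matrix(255 - unclass(gray), scheme = "cmy_gray")
}

#' Region-of-interest specification for a spot image
#'
#' @param mode One of `"full"` (all pixels), `"circle"` (explicit disc) or
#'   `"auto"` (detected disc).
#' @param center Numeric length-2 `(row, col)` pixel centre (1-based,
#'   row-major), required for circle/auto.
#' @param radius Disc radius in pixels.
#' @param margin_fraction Fraction in \[0, 0.5) by which an automatically
#'   detected radius is shrunk to exclude edge / coffee-ring pixels.
#' @return A `roi_spec` object.
#' @export
roi_spec <- function(mode = c("auto", "full", "circle"), center = NULL,
                     radius = NULL, margin_fraction = 0.15) {
  mode <- match.arg(mode)
  if (margin_fraction < 0 || margin_fraction >= 0.5) {
    stop("margin_fraction must lie in [0, 0.5)", call. = FALSE)
  }
  if (mode == "circle") {
    if (is.null(center) || is.null(radius) || length(center) != 2L ||
        radius <= 0) {
      stop("circle ROI requires center = c(row, col) and radius > 0",
           call. = FALSE)
    }
  }
  structure(list(mode = mode, center = center, radius = radius,
                 margin_fraction = margin_fraction),
            class = "roi_spec")
}

#' @export
format.roi_spec <- function(x, ...) {
  if (x$mode == "full") "<roi_spec: full image>"
  else sprintf("<roi_spec: %s circle at (%.1f, %.1f), radius %.1f px>",
               x$mode, x$center[1], x$center[2], x$radius)
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Detect the reagent spot in a CMY gray image
#'
#' Thresholds at the background median plus three background MADs (the
#' background being the outer 10% image border), labels connected components,
#' keeps the largest component above threshold, fits its enclosing circle
#' (centroid plus maximal centre-to-member distance), and shrinks the radius
#' by `margin_fraction` to exclude edge and coffee-ring pixels.
#'
#' @param gray A [gray_matrix()] with scheme `"cmy_gray"` containing one
#'   dark spot on a lighter background.
#' @param margin_fraction Radius shrink fraction, default 0.15.
#' @return A [roi_spec()] with `mode = "auto"`.
#' @export
detect_spot_roi <- function(gray, margin_fraction = 0.15) {
  stopifnot(inherits(gray, "gray_matrix"))
  if (gray_scheme(gray) != "cmy_gray") {
    stop("spot detection expects a cmy_gray matrix (dark spot = high value)",
         call. = FALSE)
  }
  v <- unclass(gray)
  h <- nrow(v); w <- ncol(v)
  b <- pmax(1L, round(0.1 * c(h, w)))
  border_mask <- matrix(FALSE, h, w)
  border_mask[c(seq_len(b[1]), h - seq_len(b[1]) + 1L), ] <- TRUE
  border_mask[, c(seq_len(b[2]), w - seq_len(b[2]) + 1L)] <- TRUE
  bg <- v[border_mask]
  thr <- stats::median(bg) + 3 * stats::mad(bg)
  mask <- v > thr
  if (!any(mask)) stop("no spot detected", call. = FALSE)

  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  sizes <- tabulate(lab[lab > 0])
  comp <- which.max(sizes)
  in_comp <- lab == comp

  perimeter <- 2L * (h + w) - 4L
  n_edge <- sum(in_comp[1, ]) + sum(in_comp[h, ]) +
    sum(in_comp[2:(h - 1), 1]) + sum(in_comp[2:(h - 1), w])
  if (n_edge > 0.5 * perimeter) {
    stop("spot not separable from background", call. = FALSE)
  }

  idx <- which(in_comp, arr.ind = TRUE)
  ctr <- colMeans(idx)
  r_enclose <- sqrt(max((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2))
  roi_spec(mode = "auto", center = unname(ctr),
           radius = r_enclose * (1 - margin_fraction),
           margin_fraction = margin_fraction)
}

#' Extract pixel gray values inside a region of interest
#'
#' Disc membership is decided by pixel-centre distance: pixel `(r, c)` is
#' inside when `(r - row)^2 + (c - col)^2 <= radius^2`.
#'
#' @param gray A [gray_matrix()].
#' @param roi A [roi_spec()]; for `mode = "full"` every pixel is returned.
#' @return Numeric vector of gray values inside the ROI, with attribute
#'   `n_pixels` (its length).
#' @export
extract_roi <- function(gray, roi) {
  stopifnot(inherits(gray, "gray_matrix"), inherits(roi, "roi_spec"))
  v <- unclass(gray)
  if (roi$mode == "full") {
    vals <- as.numeric(v)
  } else {
    rows <- matrix(seq_len(nrow(v)), nrow(v), ncol(v))
    cols <- matrix(seq_len(ncol(v)), nrow(v), ncol(v), byrow = TRUE)
    inside <- (rows - roi$center[1])^2 + (cols - roi$center[2])^2 <=
      roi$radius^2
    vals <- v[inside]
  }
  if (length(vals) == 0L) stop("empty ROI", call. = FALSE)
  attr(vals, "n_pixels") <- length(vals)
  vals
}

#' Parse a command-line ROI description
#'
#' Accepts `"full"`, `"auto"`, or `"circle:row,col,radius"`.
#'
#' @param text ROI description string.
#' @return A [roi_spec()].
#' @export
parse_roi <- function(text) {
  if (inherits(text, "roi_spec")) return(text)
  if (identical(text, "full")) return(roi_spec("full"))
  if (identical(text, "auto")) return(roi_spec("auto"))
  if (grepl("^circle:", text)) {
    nums <- suppressWarnings(as.numeric(strsplit(sub("^circle:", "", text),
                                                 ",")[[1]]))
    if (length(nums) != 3L || anyNA(nums)) {
      stop("circle ROI must be 'circle:row,col,radius'", call. = FALSE)
    }
    return(roi_spec("circle", center = nums[1:2], radius = nums[3]))
  }
  stop(sprintf("unrecognised ROI '%s'", text), call. = FALSE)
}
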