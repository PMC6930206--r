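#' Construct a B-scan object
#'
#' A `bscan` wraps a 2-D intensity raster together with its scan geometry.
#' Row 1 is the vitreous (top of the image); row indices increase toward the
#' choroid. All windows used by the package are 1-based and inclusive.
#'
#' @param pixels Numeric matrix of non-negative, finite intensities
#'   (rows = depth, columns = lateral position).
#' @param lateral_um_per_px Lateral pixel pitch in micrometres per pixel.
#' @param axial_um_per_px Axial pixel pitch in micrometres per pixel.
#' @param scan_id Opaque label for the scan.
#' @param meridian `"horizontal"` or `"vertical"`.
#' @param is_log_transformed Logical; `TRUE` when the pixel values are already
#'   on the logarithmic working scale used for quantification.
#' @param center_col Column index of the foveal centre; defaults to the image
#'   centre when `NULL`.
#' @param scan_pos_um Signed position of this line scan along the orthogonal
#'   meridian (micrometres from the fovea); used when assembling en-face maps.
#'
#' @return An object of class `bscan`.
#' @export
#' @examples
#' img <- bscan(matrix(runif(64 * 64), 64), 11.7, 3.87)
#' img
bscan <- function(pixels, lateral_um_per_px, axial_um_per_px,
                  scan_id = "scan", meridian = c("horizontal", "vertical"),
                  is_log_transformed = FALSE, center_col = NULL,
                  scan_pos_um = 0) {
  meridian <- match.arg(meridian)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.", class = "meziq_error_validation")
  }
  if (anyNA(pixels) || any(!is.finite(pixels)) || any(pixels < 0)) {
    abort("`pixels` must be finite and non-negative.",
          class = "meziq_error_validation")
  }
  if (!is.numeric(lateral_um_per_px) || lateral_um_per_px <= 0 ||
      !is.numeric(axial_um_per_px) || axial_um_per_px <= 0) {
    abort("Pixel pitches must be positive.", class = "meziq_error_validation")
  }
  structure(
    list(pixels = pixels,
         lateral_um_per_px = as.numeric(lateral_um_per_px),
         axial_um_per_px = as.numeric(axial_um_per_px),
         scan_id = scan_id,
         meridian = meridian,
         is_log_transformed = isTRUE(is_log_transformed),
         center_col = if (is.null(center_col)) NULL else as.integer(center_col),
         scan_pos_um = as.numeric(scan_pos_um)),
    class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<bscan '%s'> %d x %d px (%.0f x %.0f um), %s, %slog scale\n",
    x$scan_id, d[1], d[2],
    d[1] * x$axial_um_per_px, d[2] * x$lateral_um_per_px,
    x$meridian, if (x$is_log_transformed) "" else "not "))
  invisible(x)
}

#' @export
dim.bscan <- function(x) dim(x$pixels)

#' Logarithmic intensity transform
#'
#' Maps pixel values by `v -> log(1 + v)` and (by default) rescales the result
#' back to the original dynamic range so downstream thresholds stay on a
#' familiar scale. The map is strictly monotone, so it never changes which row
#' holds the intensity maximum of a column. Applying it to an
#' already-transformed scan is a no-op with a warning; the image is never
#' double-transformed.
#'
#' @param image A [bscan()].
#' @param rescale Rescale the transformed values so the image maximum is
#'   unchanged (default `TRUE`).
#' @return A [bscan()] on the working (log) scale.
#' @export
log_transform <- function(image, rescale = TRUE) {
  stopifnot(inherits(image, "bscan"))
  if (image$is_log_transformed) {
    warn("Image is already log-transformed; returning it unchanged.")
    return(image)
  }
  p <- image$pixels
  mx <- max(p)
  q <- log1p(p)
  if (rescale && mx > 0) q <- q * (mx / log1p(mx))
  image$pixels <- q
  image$is_log_transformed <- TRUE
  image
}

#' Invert the logarithmic transform
#'
#' Recovers linear-scale intensities from a working-scale image produced by
#' [log_transform()]. `original_max` must be the linear-scale maximum the
#' rescaling used (for `rescale = TRUE`); phantoms exported on the linear
#' scale use this to round-trip exactly.
#'
#' @param image A log-scale [bscan()].
#' @param original_max Linear-scale maximum used when rescaling, or `NULL`
#'   when the transform was applied with `rescale = FALSE`.
#' @return A linear-scale [bscan()].
#' @export
inverse_log_transform <- function(image, original_max = NULL) {
  stopifnot(inherits(image, "bscan"))
  if (!image$is_log_transformed) {
    warn("Image is not log-transformed; returning it unchanged.")
    return(image)
  }
  q <- image$pixels
  if (!is.null(original_max) && original_max > 0) {
    q <- q * (log1p(original_max) / original_max)
  }
  image$pixels <- pmax(expm1(q), 0)
  image$is_log_transformed <- FALSE
  image
}

#' Crop the central analysis region of a scan
#'
#' Returns a laterally cropped scan spanning `extent_um` centred on
#' `center_col` (the foveal column). The crop width is `extent_um` divided by
#' the lateral pixel pitch, rounded to the nearest pixel count; the axial
#' extent is unchanged. The EZ becomes less distinct with eccentricity, so
#' quantification is restricted to the central 4000 um by default.
#'
#' @param image A [bscan()].
#' @param center_col Foveal column index; defaults to `image$center_col`, or
#'   the image centre.
#' @param extent_um Lateral extent of the analysis region, micrometres.
#' @return A cropped [bscan()]; `center_col` is remapped into the crop.
#' @export
crop_central_region <- function(image, center_col = NULL, extent_um = 4000) {
  stopifnot(inherits(image, "bscan"))
  w <- ncol(image$pixels)
  center_col <- center_col %||% image$center_col %||% ((w + 1L) %/% 2L)
  center_col <- as.integer(center_col)
  if (center_col < 1L || center_col > w) {
    abort("`center_col` lies outside the image.",
          class = "meziq_error_validation")
  }
  n_cols <- as.integer(round(extent_um / image$lateral_um_per_px))
  if (n_cols > w) {
    abort(sprintf(
      "Requested extent (%d columns) exceeds image width (%d columns) by %d.",
      n_cols, w, n_cols - w), class = "meziq_error_validation")
  }
  lo <- center_col - n_cols %/% 2L
  hi <- lo + n_cols - 1L
  if (lo < 1L || hi > w) {
    short <- max(1L - lo, hi - w)
    abort(sprintf(
      "Crop of %d columns centred on column %d crosses the image edge by %d px.",
      n_cols, center_col, short), class = "meziq_error_validation")
  }
  image$pixels <- image$pixels[, lo:hi, drop = FALSE]
  image$center_col <- center_col - lo + 1L
  image
}

#' Read a grayscale B-scan from TIFF or PNG
#'
#' Supports 8- and 16-bit grayscale images. Values are rescaled to the
#' native integer range (0..255 or 0..65535). Scan geometry is not stored in
#' these formats and must be supplied.
#'
#' @inheritParams bscan
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param ... Passed on to [bscan()].
#' @return A [bscan()].
#' @export
read_bscan <- function(path, lateral_um_per_px, axial_um_per_px, ...) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    m <- png::readPNG(path, info = TRUE)
    # readPNG returns [0,1]; restore the integer scale of the source depth
    depth <- attr(m, "info")$bit.depth %||% 8L
    m <- m * (2^depth - 1)
  } else {
    abort(sprintf("Unsupported image format '%s'.", ext),
          class = "meziq_error_io")
  }
  if (length(dim(m)) == 3L) m <- m[, , 1]
  bscan(m, lateral_um_per_px = lateral_um_per_px,
        axial_um_per_px = axial_um_per_px, ...)
}

#' Write a B-scan as 16-bit TIFF or 8-bit PNG
#'
#' @param image A [bscan()].
#' @param path Output path (`.tif`/`.tiff` or `.png`).
#' @param max_value Intensity mapped to the top of the 16-bit range; defaults
#'   to the image maximum (or 1 for an all-zero image).
#' @return `path`, invisibly.
#' @export
write_bscan <- function(image, path, max_value = NULL) {
  stopifnot(inherits(image, "bscan"))
  mx <- max_value %||% max(image$pixels, 1)
  m <- pmin(pmax(image$pixels / mx, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    png::writePNG(m, path)
  } else {
    abort(sprintf("Unsupported image format '%s'.", ext),
          class = "meziq_error_io")
  }
  invisible(path)
}
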