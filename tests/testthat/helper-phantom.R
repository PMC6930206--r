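# Small phantoms keep the unit tests fast; acceptance tests use full-size
# scans. 256 columns over 4500 um is 17.6 um/px laterally; 128 rows at
# 3.87 um/px give 495 um of depth, enough for the outer complex at
# 250-340 um.
quick_spec <- function(...) {
  phantom_spec(width_px = 256L, height_px = 128L,
               lateral_scan_len_um = 4500, ...)
}

quick_extraction <- function(spec = quick_spec(), extent_um = 4000, ...) {
  ph <- generate_bscan(spec, extent_um = extent_um)
  list(extraction = quantify_bscan(ph$image, extent_um = extent_um, ...),
       truth = ph$truth)
}

# Hand-built band_extraction for testing the sector arithmetic in isolation.
fake_extraction <- function(elm_peak, ez_peak, valid = NULL, reason = NULL,
                            lateral_um_per_px = 10,
                            center = (length(elm_peak) + 1) / 2) {
  w <- length(elm_peak)
  valid <- valid %||% rep(TRUE, w)
  reason <- reason %||% ifelse(valid, "none", "no_valid_peak")
  structure(
    list(columns = tibble::tibble(
           col = seq_len(w),
           lateral_um = (seq_len(w) - center) * lateral_um_per_px,
           elm_depth_px = 10L, elm_peak = elm_peak,
           ez_depth_px = 20L, ez_peak = ez_peak,
           valid = valid, reason = reason),
         crop_window = c(row_lo = 1L, row_hi = 30L, col_lo = 1L, col_hi = w),
         n_rows = 30L, lateral_um_per_px = lateral_um_per_px,
         axial_um_per_px = 4, scan_id = "fake", meridian = "horizontal",
         scan_pos_um = 0, min_valid_frac = 0.5, failed = FALSE),
    class = "band_extraction")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force Deming oracle: 1-D golden grid over the slope with the
# intercept profiled out analytically (for fixed slope b the oblique
# distance sum is minimised by a = ybar - b*xbar), refined until the slope
# bracket is below `tol`. Independent of the closed-form estimator.
deming_grid_oracle <- function(x, y, lambda = 1, lo = -10, hi = 10,
                               tol = 1e-9) {
  obj <- function(b) {
    a <- mean(y) - b * mean(x)
    sum((y - a - b * x)^2) / (lambda + b^2)
  }
  while (hi - lo > tol) {
    grid <- seq(lo, hi, length.out = 201)
    vals <- vapply(grid, obj, numeric(1))
    k <- which.min(vals)
    lo <- grid[max(1, k - 1)]
    hi <- grid[min(length(grid), k + 1)]
  }
  b <- (lo + hi) / 2
  c(slope = b, intercept = mean(y) - b * mean(x))
}

# A uniform 21-sector table with given value, for aggregation tests.
flat_sectors <- function(value, n = 21, scan_id = "s", scan_pos_um = 0,
                         meridian = "horizontal") {
  tibble::tibble(scan_id = scan_id, meridian = meridian,
                 scan_pos_um = scan_pos_um, sector_id = seq_len(n),
                 lateral_center_um = seq(-2000, 2000, length.out = n),
                 mezi = value, excluded = FALSE, exclusion_reason = "none")
}
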