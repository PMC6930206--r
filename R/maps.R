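#' Build an en-face mEZi map from sector measurements
#'
#' Assembles the per-sector EZ/ELM ratios of the horizontal and vertical line
#' scans into a topographic lattice over the central macular square. Each
#' horizontal scan contributes a row of values (its `scan_pos_um` is its
#' vertical position), each vertical scan a column. Along every measured line
#' the sector values are linearly interpolated to the lattice axis (excluded
#' sectors are filled from their neighbours); between measured lines the two
#' line fields are linearly interpolated and averaged where both meridians
#' supply a value. Interpolation is convex — no lattice cell falls outside
#' the range of the measured values — and cells not backed by a direct
#' measurement are flagged in `interpolation_mask`. Each measurement is also
#' written into its nearest lattice cell, so measured cells carry their
#' source value (cells where a horizontal and a vertical sector collide store
#' the mean of the two).
#'
#' @param horizontal_scans,vertical_scans Sector tibbles (as returned by
#'   [am_quantify_scan()]) or lists of them; `scan_pos_um` must give each
#'   line's signed offset from the fovea. Vertical scans may be omitted.
#' @param n_grid Lattice dimension (`n_grid` x `n_grid` cells).
#' @param extent_um Physical side length of the mapped square, micrometres.
#' @param color_scale Length-2 mEZi range mapped onto the colour ramp;
#'   defaults to the 1st-99th percentile of the lattice.
#' @return An object of class `mezi_map`: `grid` (matrix, row 1 = superior),
#'   `interpolation_mask`, `color_scale`, `axis_um` (cell-centre
#'   coordinates), and `measurements` (the source records).
#' @export
build_mezi_map <- function(horizontal_scans, vertical_scans = NULL,
                           n_grid = 220L, extent_um = 4000,
                           color_scale = NULL) {
  hs <- normalize_scans(horizontal_scans)
  vs <- normalize_scans(vertical_scans)
  if (!length(hs) && !length(vs)) {
    abort("No usable scans supplied.", class = "meziq_error_validation")
  }
  axis_um <- -extent_um / 2 + (seq_len(n_grid) - 0.5) * (extent_um / n_grid)

  # field built from one meridian: interpolate along each line, then across
  # the lines' positions; constant extension beyond the outermost lines
  meridian_field <- function(scans, transpose) {
    if (!length(scans)) return(NULL)
    pos <- map_dbl(scans, ~ .x$scan_pos_um[1])
    o <- order(pos)
    scans <- scans[o]; pos <- pos[o]
    lines <- map(scans, function(s) {
      u <- s[!s$excluded & !is.na(s$mezi), ]
      if (nrow(u) < 1) return(rep(NA_real_, n_grid))
      if (nrow(u) == 1) return(rep(u$mezi, n_grid))
      stats::approx(u$lateral_center_um, u$mezi, xout = axis_um,
                    rule = 2)$y
    })
    L <- do.call(rbind, lines)
    keep <- rowSums(is.na(L)) == 0
    L <- L[keep, , drop = FALSE]; pos <- pos[keep]
    if (!nrow(L)) return(NULL)
    if (anyDuplicated(pos)) {  # repeated line positions: average them
      L <- rowsum(L, group = pos) / as.vector(table(pos))
      pos <- sort(unique(pos))
    }
    field <- apply(L, 2, function(colv) {
      if (length(pos) == 1) rep(colv, n_grid)
      else stats::approx(pos, colv, xout = axis_um, rule = 2)$y
    })
    if (transpose) t(field) else field
  }

  fh <- meridian_field(hs, transpose = FALSE)  # rows vary with y
  fv <- meridian_field(vs, transpose = TRUE)
  grid <- if (is.null(fh)) fv else if (is.null(fv)) fh else (fh + fv) / 2
  if (is.null(grid)) {
    abort("No usable scans supplied.", class = "meziq_error_validation")
  }

  # overwrite cells backed by a direct measurement with their source values
  meas <- bind_rows(
    map(hs, ~ mutate(.x, .row_um = .x$scan_pos_um, .col_um = .x$lateral_center_um)),
    map(vs, ~ mutate(.x, .row_um = .x$lateral_center_um, .col_um = .x$scan_pos_um)))
  meas <- meas[!meas$excluded & !is.na(meas$mezi), ]
  nearest <- function(u) {
    pmin(pmax(floor((u + extent_um / 2) / (extent_um / n_grid)) + 1L, 1L),
         n_grid)
  }
  mask <- matrix(TRUE, n_grid, n_grid)
  if (nrow(meas)) {
    ri <- nearest(meas$.row_um); ci <- nearest(meas$.col_um)
    cell <- (ci - 1L) * n_grid + ri
    cell_mean <- tapply(meas$mezi, cell, mean)
    grid[as.integer(names(cell_mean))] <- as.numeric(cell_mean)
    mask[as.integer(names(cell_mean))] <- FALSE
  }

  color_scale <- color_scale %||%
    as.numeric(quantile(grid, c(0.01, 0.99), na.rm = TRUE))
  structure(
    list(grid = grid, interpolation_mask = mask, color_scale = color_scale,
         axis_um = axis_um, extent_um = extent_um,
         measurements = meas[, setdiff(names(meas), c(".row_um", ".col_um"))]),
    class = "mezi_map")
}

normalize_scans <- function(x) {
  if (is.null(x)) return(list())
  if (is.data.frame(x)) x <- list(x)
  keep(compact(x), ~ is.data.frame(.x) && nrow(.x) > 0)
}

#' Mean mEZi over measured cells
#'
#' The mean over the map's source sector measurements; equals the pooled
#' per-eye mEZi of the same sectors.
#'
#' @param map A `mezi_map`.
#' @return A number.
#' @export
map_measured_mean <- function(map) {
  stopifnot(inherits(map, "mezi_map"))
  mean(map$measurements$mezi)
}

#' @export
print.mezi_map <- function(x, ...) {
  cat(sprintf(
    "<mezi_map> %d x %d cells over %.0f um, %d measurements, scale [%.2f, %.2f]\n",
    nrow(x$grid), ncol(x$grid), x$extent_um, nrow(x$measurements),
    x$color_scale[1], x$color_scale[2]))
  invisible(x)
}

# blue (low) -> yellow (high) ramp on [0, 1]; NA -> grey
mezi_ramp <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  r <- t; g <- t; b <- 1 - t
  na <- is.na(t)
  r[na] <- 0.5; g[na] <- 0.5; b[na] <- 0.5
  list(r = r, g = g, b = b)
}

#' Render an mEZi map to a PNG file
#'
#' Greater mEZi is yellow, smaller is blue; a vertical colourbar is appended
#' on the right. Output bytes are a deterministic function of the map, so
#' repeated renders of the same map are identical.
#'
#' @param map A `mezi_map`.
#' @param path Output `.png` path.
#' @param width_px Rendered width of the map panel (nearest-neighbour
#'   upsampling; the colourbar adds ~7% width).
#' @return `path`, invisibly.
#' @export
render_mezi_map <- function(map, path, width_px = 512L) {
  stopifnot(inherits(map, "mezi_map"))
  sc <- map$color_scale
  rng <- if (diff(sc) > 0) diff(sc) else 1
  tgrid <- (map$grid - sc[1]) / rng
  idx <- round(seq(1, nrow(map$grid), length.out = width_px))
  big <- tgrid[idx, idx, drop = FALSE]
  bar <- matrix(rev(seq(0, 1, length.out = width_px)),
                nrow = width_px, ncol = max(16L, width_px %/% 16L))
  gapw <- max(4L, width_px %/% 128L)
  gap <- matrix(NA_real_, width_px, gapw)
  panel <- cbind(big, gap, bar)
  col <- mezi_ramp(panel)
  arr <- array(c(col$r, col$g, col$b), dim = c(dim(panel), 3L))
  # the gap renders white rather than the NA grey
  gap_cols <- (ncol(big) + 1):(ncol(big) + gapw)
  arr[, gap_cols, ] <- 1
  png::writePNG(arr, path)
  invisible(path)
}

#' @rdname build_mezi_map
#' @param object A `mezi_map`.
#' @param ... Unused.
#' @export
autoplot.mezi_map <- function(object, ...) {
  d <- expand.grid(y = object$axis_um, x = object$axis_um)
  d$mezi <- as.vector(object$grid)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = -.data$y,
                                  fill = .data$mezi)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "blue", high = "yellow",
                                 limits = object$color_scale,
                                 oob = scales_squish) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Temporal-nasal (µm)",
                  y = "Inferior-superior (µm)", fill = "mEZi") +
    ggplot2::theme_minimal()
}

# minimal squish so the scales package need not be attached explicitly
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}
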