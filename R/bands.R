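#' Otsu histogram threshold
#'
#' Global histogram split maximising between-class variance, computed on a
#' 256-bin histogram over the image range. Used to separate the reflective
#' retinal bands from the dark background/vitreous before locating the outer
#' retinal complex.
#'
#' @param pixels Numeric matrix or vector of non-negative intensities.
#' @param n_bins Number of histogram bins.
#' @return The threshold, on the intensity scale of `pixels`.
#' @export
otsu_threshold <- function(pixels, n_bins = 256L) {
  v <- as.numeric(pixels)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  width <- (hi - lo) / n_bins
  idx <- pmin(floor((v - lo) / width), n_bins - 1)
  counts <- tabulate(idx + 1L, nbins = n_bins)
  p <- counts / sum(counts)
  mids <- lo + (seq_len(n_bins) - 0.5) * width
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  # empty histogram gaps give a plateau of maxima; take its midpoint
  ks <- which(sigma_b >= max(sigma_b) - 1e-12)
  k <- mean(range(ks))
  lo + k * width  # upper edge of the chosen bin: v > threshold is foreground
}

# Per-column suprathreshold runs, merged across gaps shorter than
# `merge_gap_px`; returns the deepest merged run as c(start, end) or NULL.
deepest_complex <- function(col_vals, threshold, merge_gap_px) {
  r <- rle(col_vals > threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  if (!length(on)) return(NULL)
  s <- starts[on]; e <- ends[on]
  if (length(on) > 1L) {
    gaps <- s[-1] - e[-length(e)] - 1L
    brk <- which(gaps >= merge_gap_px)
    grp <- cumsum(c(0L, seq_along(gaps) %in% brk))
    s <- tapply(s, grp, min)
    e <- tapply(e, grp, max)
  }
  c(s[length(s)], e[length(e)])
}

#' Remove the inner retina and isolate the outer retinal complex
#'
#' Thresholds the (log-scale, cropped) B-scan with [otsu_threshold()], finds
#' per A-scan the contiguous suprathreshold runs, merges runs separated by
#' less than `merge_gap_um` (the ELM/EZ/RPE bands are close enough that their
#' flank troughs can dip under the threshold), and keeps the *deepest* merged
#' run — the outer retinal complex. Everything above (and below) it is zeroed,
#' which removes the inner-retina complex. The operation is idempotent.
#'
#' @param image A log-scale [bscan()], already cropped to the analysis extent.
#' @param merge_gap_um Runs closer than this (axially) are one complex.
#' @param margin_px Rows kept on each side of the complex so band flanks
#'   survive for sub-pixel peak refinement.
#' @param run_threshold_frac The run threshold is this fraction of the Otsu
#'   split. The Otsu split on a mostly-dark B-scan separates background from
#'   the *bright* band mass and can sit above the ELM — the dimmest band the
#'   method measures — so runs are taken at a fraction of it, which keeps the
#'   ELM inside the retained complex while staying far above background.
#' @param min_valid_frac If fewer than this fraction of columns contain a
#'   suprathreshold run the scan is marked failed.
#' @return A list: `image` (outer-complex-only [bscan()]), `crop_window`
#'   (`c(row_lo, row_hi, col_lo, col_hi)`, 1-based inclusive bounds of the
#'   retained region), `column_found` (logical per column), `threshold`, and
#'   `failed`.
#' @export
eliminate_inner_retina <- function(image, merge_gap_um = 50, margin_px = 2L,
                                   run_threshold_frac = 0.5,
                                   min_valid_frac = 0.5) {
  stopifnot(inherits(image, "bscan"))
  if (!image$is_log_transformed) {
    warn("Expected a log-transformed image; proceeding on the given scale.")
  }
  p <- image$pixels
  h <- nrow(p); w <- ncol(p)
  # an already-eliminated image carries the threshold it was cut with;
  # reusing it makes the operation exactly idempotent
  thr <- image$elim_threshold %||% (run_threshold_frac * otsu_threshold(p))
  gap_px <- max(1L, as.integer(round(merge_gap_um / image$axial_um_per_px)))

  out <- matrix(0, h, w)
  found <- logical(w)
  row_lo <- h + 1L; row_hi <- 0L
  for (j in seq_len(w)) {
    run <- deepest_complex(p[, j], thr, gap_px)
    if (is.null(run)) next
    found[j] <- TRUE
    s <- max(1L, run[1] - margin_px)
    e <- min(h, run[2] + margin_px)
    out[s:e, j] <- p[s:e, j]
    row_lo <- min(row_lo, s); row_hi <- max(row_hi, e)
  }
  failed <- mean(found) < min_valid_frac
  if (!any(found)) { row_lo <- 1L; row_hi <- h }
  image$pixels <- out
  image$elim_threshold <- thr
  list(image = image,
       crop_window = c(row_lo = row_lo, row_hi = row_hi,
                       col_lo = 1L, col_hi = w),
       column_found = found, threshold = thr, failed = failed)
}

# 3-point parabolic refinement of a local maximum at index i.
# Returns c(offset_px, peak_value); falls back to the raw sample when the
# neighbourhood is not concave.
refine_peak <- function(v, i) {
  if (i <= 1L || i >= length(v)) return(c(0, v[i]))
  a <- v[i - 1L]; b <- v[i]; c_ <- v[i + 1L]
  den <- a - 2 * b + c_
  if (den >= 0) return(c(0, b))
  d <- 0.5 * (a - c_) / den
  d <- max(min(d, 0.5), -0.5)
  c(d, b - 0.25 * (a - c_) * d)
}

#' Extract the ELM and EZ intensity peaks per A-scan
#'
#' Within the retained outer-complex region of each column, finds local
#' intensity maxima above a floor (a fraction of the column maximum). The
#' shallowest qualifying peak is the ELM; the next deeper qualifying peak
#' whose axial separation from the ELM lies in `gap_um` is the EZ. The
#' separation window (default 10–80 um) stops the RPE — typically ~90 um
#' below the ELM — from being mistaken for the EZ. Peak intensities are read
#' with 3-point parabolic sub-pixel refinement so a peak falling between
#' pixel centres is not under-read. Columns with fewer than two peaks, or
#' violating the ordering/separation constraints, are invalid.
#'
#' @param image The outer-complex [bscan()] from [eliminate_inner_retina()].
#' @param window The `crop_window` from [eliminate_inner_retina()].
#' @param gap_um Length-2 plausible ELM-to-EZ axial separation, micrometres.
#' @param peak_floor_frac Peaks below this fraction of the column maximum are
#'   ignored.
#' @param min_valid_frac Scans with fewer valid columns than this fraction
#'   are marked `failed`.
#' @return An object of class `band_extraction`: a list with `columns` (a
#'   tibble with one row per A-scan: `col`, `lateral_um` signed eccentricity,
#'   `elm_depth_px`, `elm_peak`, `ez_depth_px`, `ez_peak`, `valid`, `reason`),
#'   `crop_window`, `failed`, `n_rows`, and the scan geometry.
#' @export
extract_bands <- function(image, window, gap_um = c(10, 80),
                          peak_floor_frac = 0.1, min_valid_frac = 0.5) {
  stopifnot(inherits(image, "bscan"), length(gap_um) == 2)
  p <- image$pixels
  h <- nrow(p); w <- ncol(p)
  rows <- window[["row_lo"]]:window[["row_hi"]]
  axpx <- image$axial_um_per_px
  center <- image$center_col %||% ((w + 1L) / 2)
  lateral_um <- (seq_len(w) - center) * image$lateral_um_per_px

  elm_d <- ez_d <- rep(NA_integer_, w)
  elm_v <- ez_v <- rep(NA_real_, w)
  valid <- logical(w)
  for (j in seq_len(w)) {
    v <- p[rows, j]
    mx <- max(v)
    if (mx <= 0) next
    floor_j <- peak_floor_frac * mx
    nv <- length(v)
    is_pk <- c(FALSE, v[2:(nv - 1)] >= v[1:(nv - 2)] &
                 v[2:(nv - 1)] > v[3:nv], FALSE) & v >= floor_j
    pk <- which(is_pk)
    if (length(pk) < 2L) next
    elm_i <- pk[1]
    deeper <- pk[pk > elm_i]
    gaps <- (deeper - elm_i) * axpx
    cand <- deeper[gaps >= gap_um[1]]
    if (!length(cand)) next
    ez_i <- cand[1]
    if ((ez_i - elm_i) * axpx > gap_um[2]) next
    re <- refine_peak(v, elm_i)
    rz <- refine_peak(v, ez_i)
    if (re[2] <= 0 || rz[2] <= 0) next
    elm_d[j] <- rows[1] + elm_i - 1L
    ez_d[j] <- rows[1] + ez_i - 1L
    elm_v[j] <- re[2]
    ez_v[j] <- rz[2]
    valid[j] <- TRUE
  }
  columns <- tibble(col = seq_len(w), lateral_um = lateral_um,
                    elm_depth_px = elm_d, elm_peak = elm_v,
                    ez_depth_px = ez_d, ez_peak = ez_v,
                    valid = valid,
                    reason = ifelse(valid, "none", "no_valid_peak"))
  res <- structure(
    list(columns = columns, crop_window = window,
         n_rows = h,
         lateral_um_per_px = image$lateral_um_per_px,
         axial_um_per_px = axpx,
         scan_id = image$scan_id, meridian = image$meridian,
         scan_pos_um = image$scan_pos_um,
         min_valid_frac = min_valid_frac,
         failed = FALSE),
    class = "band_extraction")
  res$failed <- detect_failure(res)
  res
}

#' @export
print.band_extraction <- function(x, ...) {
  cat(sprintf(
    "<band_extraction '%s'> %d columns, %.1f%% valid%s\n",
    x$scan_id, nrow(x$columns), 100 * mean(x$columns$valid),
    if (x$failed) ", FAILED" else ""))
  invisible(x)
}

#' Flag vessel-shadowed A-scans
#'
#' Retinal vessels cast dark columns over the outer bands; the EZ/ELM ratio
#' is unreliable there (and can even look normal, since attenuation cancels
#' in the ratio), so shadowed columns must be excluded on absolute signal.
#' The per-column energy (summed intensity over the outer-complex rows) is
#' compared with a robust threshold, `median - k * MAD`; columns below it are
#' invalidated and each contiguous run of invalid columns is dilated by
#' `dilate` columns on both sides to catch the shadow penumbra.
#'
#' @param image The outer-complex [bscan()] used for the extraction.
#' @param extraction A `band_extraction`.
#' @param k Robustness multiplier on the MAD.
#' @param dilate Columns of dilation on each side of an invalid run.
#' @return The updated `band_extraction` (columns flagged
#'   `reason = "vessel_shadow"`, `failed` re-evaluated).
#' @export
detect_vessel_shadows <- function(image, extraction, k = 3, dilate = 1L) {
  stopifnot(inherits(image, "bscan"), inherits(extraction, "band_extraction"))
  win <- extraction$crop_window
  rows <- win[["row_lo"]]:win[["row_hi"]]
  energy <- colSums(image$pixels[rows, , drop = FALSE])
  med <- median(energy)
  thr <- med - k * mad(energy)
  shadowed <- energy < thr
  if (any(shadowed) && dilate > 0L) {
    r <- rle(shadowed)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      lo <- max(1L, starts[i] - dilate)
      hi <- min(length(shadowed), ends[i] + dilate)
      shadowed[lo:hi] <- TRUE
    }
  }
  cols <- extraction$columns
  cols$valid[shadowed] <- FALSE
  cols$reason[shadowed] <- "vessel_shadow"
  extraction$columns <- cols
  extraction$failed <- detect_failure(extraction)
  extraction
}

#' Decide whether quantification failed for a scan
#'
#' A scan is failed when (a) fewer than `min_valid_frac` of its A-scans have
#' a valid ELM/EZ peak pair, or (b) the detected EZ depth spans more than
#' `max_depth_range_frac` of the image height across the crop — the signature
#' of a highly curved posterior pole whose bands leave the frame, the failure
#' mode the automated method exhibits on strongly myopic eyes. A failed scan
#' contributes no sectors downstream.
#'
#' @param extraction A `band_extraction`.
#' @param min_valid_frac Minimum fraction of valid columns.
#' @param max_depth_range_frac Maximum allowed EZ-depth range, as a fraction
#'   of image height.
#' @return `TRUE` if the scan should be discarded.
#' @export
detect_failure <- function(extraction, min_valid_frac = NULL,
                           max_depth_range_frac = 0.4) {
  stopifnot(inherits(extraction, "band_extraction"))
  min_valid_frac <- min_valid_frac %||% extraction$min_valid_frac %||% 0.5
  cols <- extraction$columns
  frac_valid <- mean(cols$valid)
  if (frac_valid < min_valid_frac) return(TRUE)
  d <- cols$ez_depth_px[cols$valid]
  if (length(d) >= 2L) {
    if (diff(range(d)) > max_depth_range_frac * extraction$n_rows) return(TRUE)
  }
  FALSE
}
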