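#' EZ/ELM ratio over a column range
#'
#' The per-window statistic of the manual protocol: the highest EZ peak
#' intensity over the window's valid A-scans divided by the highest ELM peak
#' intensity. Returns `NA` (with a reason) when the window holds no valid
#' column.
#'
#' @param extraction A `band_extraction`.
#' @param col_lo,col_hi 1-based inclusive column range within the crop.
#' @return A list: `mezi` (numeric or `NA`), `excluded` (logical),
#'   `exclusion_reason` (`"none"`, `"vessel_shadow"` or `"no_valid_peak"`),
#'   `n_columns` used.
#' @export
compute_sector_ratio <- function(extraction, col_lo, col_hi) {
  stopifnot(inherits(extraction, "band_extraction"))
  cols <- extraction$columns
  if (col_lo < 1L || col_hi > nrow(cols) || col_lo > col_hi) {
    abort("Column range lies outside the crop.",
          class = "meziq_error_validation")
  }
  sub <- cols[col_lo:col_hi, ]
  ok <- sub$valid
  if (!any(ok)) {
    reason <- if (any(sub$reason == "vessel_shadow")) "vessel_shadow"
              else "no_valid_peak"
    return(list(mezi = NA_real_, excluded = TRUE,
                exclusion_reason = reason, n_columns = 0L))
  }
  elm <- max(sub$elm_peak[ok])
  if (elm <= 0) {
    return(list(mezi = NA_real_, excluded = TRUE,
                exclusion_reason = "no_valid_peak", n_columns = 0L))
  }
  list(mezi = max(sub$ez_peak[ok]) / elm, excluded = FALSE,
       exclusion_reason = "none", n_columns = sum(ok))
}

# Assign each column (by its signed eccentricity) to one of n equal half-open
# bins over [-extent/2, extent/2); a column centred exactly on a boundary goes
# to the lower-index bin.
sector_bins <- function(lateral_um, n_sectors, extent_um) {
  w <- extent_um / n_sectors
  pos <- lateral_um + extent_um / 2
  bin <- floor(pos / w)
  on_edge <- abs(pos - round(pos / w) * w) < 1e-9 & pos > 1e-9
  bin[on_edge] <- round(pos[on_edge] / w) - 1
  bin[pos < -1e-9 | bin > n_sectors - 1] <- NA
  as.integer(bin) + 1L
}

#' Automated sector-wise mEZi for one line scan
#'
#' Partitions the analysis extent into `n_sectors` equal evenly spaced
#' lateral bins (220 by default) and computes the EZ/ELM peak ratio in each
#' with [compute_sector_ratio()]. All sectors are returned; sectors without a
#' valid column are flagged excluded, never dropped.
#'
#' @param extraction A non-failed `band_extraction`.
#' @param n_sectors Number of sectors tiling the extent.
#' @param extent_um Analysis extent (defaults to the crop's full width).
#' @return A tibble with one row per sector: `scan_id`, `meridian`,
#'   `scan_pos_um`, `sector_id`, `lateral_center_um`, `mezi`, `excluded`,
#'   `exclusion_reason`.
#' @export
am_quantify_scan <- function(extraction, n_sectors = 220L, extent_um = NULL) {
  stopifnot(inherits(extraction, "band_extraction"))
  if (extraction$failed) {
    abort("Extraction is flagged failed; the scan yields no sectors.",
          class = "meziq_error_failed_scan")
  }
  cols <- extraction$columns
  extent_um <- extent_um %||%
    (nrow(cols) * extraction$lateral_um_per_px)
  bin <- sector_bins(cols$lateral_um, n_sectors, extent_um)
  w <- extent_um / n_sectors
  centers <- -extent_um / 2 + (seq_len(n_sectors) - 0.5) * w
  rows <- map(seq_len(n_sectors), function(i) {
    in_bin <- which(!is.na(bin) & bin == i)
    if (!length(in_bin)) {
      r <- list(mezi = NA_real_, excluded = TRUE,
                exclusion_reason = "no_valid_peak")
    } else {
      r <- compute_sector_ratio(extraction, min(in_bin), max(in_bin))
    }
    tibble(sector_id = i, lateral_center_um = centers[i],
           mezi = r$mezi, excluded = r$excluded,
           exclusion_reason = r$exclusion_reason)
  })
  out <- bind_rows(rows)
  out$scan_id <- extraction$scan_id
  out$meridian <- extraction$meridian
  out$scan_pos_um <- extraction$scan_pos_um
  out[, c("scan_id", "meridian", "scan_pos_um", "sector_id",
          "lateral_center_um", "mezi", "excluded", "exclusion_reason")]
}

#' Manual-protocol sector sampling for one line scan
#'
#' Emulates the manual grading geometry: 21 sampling windows of
#' `window_width_um` (150 um) centred at eccentricities 0, +/-200, ...,
#' +/-2000 um from the fovea. The outermost windows are clipped to the
#' analysis crop. Windows inside vessel shadows are excluded.
#'
#' @param extraction A non-failed `band_extraction`.
#' @param window_width_um Sample width, micrometres.
#' @param spacing_um Centre-to-centre interval, micrometres.
#' @param max_ecc_um Maximum eccentricity sampled.
#' @return A tibble as in [am_quantify_scan()], one row per window.
#' @export
mm_quantify_scan <- function(extraction, window_width_um = 150,
                             spacing_um = 200, max_ecc_um = 2000) {
  stopifnot(inherits(extraction, "band_extraction"))
  if (extraction$failed) {
    abort("Extraction is flagged failed; the scan yields no sectors.",
          class = "meziq_error_failed_scan")
  }
  centers <- seq(-max_ecc_um, max_ecc_um, by = spacing_um)
  cols <- extraction$columns
  rows <- imap(centers, function(ctr, i) {
    in_win <- which(cols$lateral_um >= ctr - window_width_um / 2 &
                      cols$lateral_um <= ctr + window_width_um / 2)
    if (!length(in_win)) {
      r <- list(mezi = NA_real_, excluded = TRUE,
                exclusion_reason = "no_valid_peak")
    } else {
      r <- compute_sector_ratio(extraction, min(in_win), max(in_win))
    }
    tibble(sector_id = i, lateral_center_um = ctr,
           mezi = r$mezi, excluded = r$excluded,
           exclusion_reason = r$exclusion_reason)
  })
  out <- bind_rows(rows)
  out$scan_id <- extraction$scan_id
  out$meridian <- extraction$meridian
  out$scan_pos_um <- extraction$scan_pos_um
  out[, c("scan_id", "meridian", "scan_pos_um", "sector_id",
          "lateral_center_um", "mezi", "excluded", "exclusion_reason")]
}

#' Aggregate sector measurements into a per-eye mEZi
#'
#' Pools all non-excluded sector values across the supplied scans (the full
#' acquisition design is 11 horizontal plus 11 vertical lines) and takes
#' their unweighted mean. Scans that failed extraction contribute nothing and
#' may be passed as `NULL`. With `method = "scan_then_eye"` each scan is
#' averaged first and the eye value is the mean of scan means.
#'
#' @param scans A sector tibble, or a list of sector tibbles / `NULL`s (one
#'   per scan).
#' @param eye_id,group Metadata carried into the result; `group` is a label
#'   only, no clinical logic is applied.
#' @param min_scans Minimum number of non-failed scans required.
#' @param method `"pooled"` (default) or `"scan_then_eye"`.
#' @return A one-row tibble: `eye_id`, `group`, `mezi`, `n_sectors_used`,
#'   `n_scans_used`, `failed`.
#' @export
quantify_eye <- function(scans, eye_id = "eye", group = "unknown",
                         min_scans = 1L,
                         method = c("pooled", "scan_then_eye")) {
  method <- match.arg(method)
  if (is.data.frame(scans)) scans <- list(scans)
  scans <- compact(scans)
  scans <- keep(scans, ~ is.data.frame(.x) && nrow(.x) > 0)
  if (length(scans) < min_scans) {
    return(tibble(eye_id = eye_id, group = group, mezi = NA_real_,
                  n_sectors_used = 0L, n_scans_used = length(scans),
                  failed = TRUE))
  }
  all_sectors <- bind_rows(scans)
  used <- all_sectors[!all_sectors$excluded & !is.na(all_sectors$mezi), ]
  if (nrow(used) == 0L) {
    return(tibble(eye_id = eye_id, group = group, mezi = NA_real_,
                  n_sectors_used = 0L, n_scans_used = length(scans),
                  failed = TRUE))
  }
  mezi <- if (method == "pooled") {
    mean(used$mezi)
  } else {
    scan_means <- map_dbl(scans, function(s) {
      u <- s[!s$excluded & !is.na(s$mezi), ]
      if (nrow(u)) mean(u$mezi) else NA_real_
    })
    mean(scan_means, na.rm = TRUE)
  }
  tibble(eye_id = eye_id, group = group, mezi = mezi,
         n_sectors_used = nrow(used), n_scans_used = length(scans),
         failed = FALSE)
}

#' Run the full single-scan quantification pipeline
#'
#' Convenience wrapper binding the stages: log transform (if needed), central
#' crop, inner-retina elimination, ELM/EZ peak extraction, vessel-shadow
#' exclusion and failure detection.
#'
#' @param image A [bscan()] (linear or working scale).
#' @param center_col Foveal column in the *input* image; defaults to the
#'   image centre.
#' @param extent_um Analysis extent, micrometres.
#' @param gap_um,peak_floor_frac,min_valid_frac Passed to [extract_bands()].
#' @param merge_gap_um Passed to [eliminate_inner_retina()].
#' @param shadow_k Passed to [detect_vessel_shadows()] as `k`.
#' @param max_depth_range_frac Passed to [detect_failure()].
#' @return A `band_extraction` (possibly flagged `failed`).
#' @export
#' @examples
#' ph <- generate_bscan(phantom_spec(width_px = 256, height_px = 128,
#'                                   lateral_scan_len_um = 4500))
#' ex <- quantify_bscan(ph$image)
#' head(am_quantify_scan(ex, n_sectors = 10))
quantify_bscan <- function(image, center_col = NULL, extent_um = 4000,
                           gap_um = c(10, 80), peak_floor_frac = 0.1,
                           min_valid_frac = 0.5, merge_gap_um = 50,
                           shadow_k = 3, max_depth_range_frac = 0.4) {
  stopifnot(inherits(image, "bscan"))
  if (!image$is_log_transformed) image <- log_transform(image)
  cropped <- crop_central_region(image, center_col = center_col,
                                 extent_um = extent_um)
  elim <- eliminate_inner_retina(cropped, merge_gap_um = merge_gap_um,
                                 min_valid_frac = min_valid_frac)
  ex <- extract_bands(elim$image, elim$crop_window, gap_um = gap_um,
                      peak_floor_frac = peak_floor_frac,
                      min_valid_frac = min_valid_frac)
  ex <- detect_vessel_shadows(elim$image, ex, k = shadow_k)
  ex$failed <- ex$failed || elim$failed ||
    detect_failure(ex, max_depth_range_frac = max_depth_range_frac)
  ex
}
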