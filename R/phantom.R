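#' Specify a synthetic OCT B-scan phantom
#'
#' Describes a multi-band A-scan intensity model of the macular outer retina:
#' four axially localised Gaussian-profile bands (inner-retina complex, ELM,
#' EZ, RPE) over a dark background, with optional multiplicative speckle,
#' additive noise and vessel-shadow columns. Band amplitudes are specified on
#' the *working* (post-log-transform) scale so the ground-truth EZ/ELM ratio
#' is exact on the scale the quantifier operates on; [generate_bscan()] can
#' export a linear-scale image for end-to-end tests through the transform.
#'
#' Band depth may be a single number (flat band), a coefficient vector
#' `c(c0, c1, c2)` giving depth `c0 + c1*u + c2*u^2` in micrometres as a
#' function of the signed lateral eccentricity `u` (micrometres from the scan
#' centre), or a function of `u`. Band amplitude may likewise be a scalar or
#' a function of `u`.
#'
#' Defaults emulate a Spectralis-like high-resolution 9-mm line scan of a
#' healthy macula: 768 A-scans at 11.72 um/px laterally, 496 px at 3.87 um/px
#' axially; ELM/EZ/RPE at 250/290/340 um with peak amplitudes 60/240/255
#' (working-scale mEZi 4.0, the normal-eye regime), and a broad inner-retina
#' complex at 120 um.
#'
#' @param width_px,height_px Raster dimensions (each at least 64).
#' @param lateral_scan_len_um Physical scan width in micrometres.
#' @param axial_um_per_px Axial pixel pitch, micrometres per pixel.
#' @param band_depths_um Named list (`inner_retina_complex`, `elm`, `ez`,
#'   `rpe`) of depths; see Details.
#' @param band_peak_values Named list or vector of peak amplitudes on the
#'   working scale (all positive); entries may be functions of eccentricity.
#' @param band_sigma_um Named vector of axial Gaussian widths (sigma), um.
#' @param noise_sd Additive Gaussian noise SD on the working scale.
#' @param speckle_factor Dispersion (sdlog) of unit-mean log-normal
#'   multiplicative speckle; 0 disables it.
#' @param vessel_shadow_columns List of `c(center_um, width_um,
#'   attenuation_fraction)` triplets; `center_um` is signed eccentricity from
#'   the scan centre and `attenuation_fraction` in (0, 1] is the fraction of
#'   signal removed below the shadow onset depth.
#' @param shadow_start_um Depth below which shadows attenuate; defaults to
#'   midway between the inner-retina and ELM band centres.
#' @param seed Integer RNG seed; identical specs yield bit-identical phantoms.
#'
#' @return An object of class `phantom_spec`.
#' @seealso [generate_bscan()]
#' @export
phantom_spec <- function(width_px = 768L, height_px = 496L,
                         lateral_scan_len_um = 9000,
                         axial_um_per_px = 3.87,
                         band_depths_um = list(inner_retina_complex = 120,
                                               elm = 250, ez = 290, rpe = 340),
                         band_peak_values = c(inner_retina_complex = 180,
                                              elm = 60, ez = 240, rpe = 255),
                         band_sigma_um = c(inner_retina_complex = 25,
                                           elm = 6, ez = 8, rpe = 10),
                         noise_sd = 0, speckle_factor = 0,
                         vessel_shadow_columns = list(),
                         shadow_start_um = NULL,
                         seed = 1L) {
  bands <- c("inner_retina_complex", "elm", "ez", "rpe")
  if (width_px < 64 || height_px < 64) {
    abort("Phantom must be at least 64 x 64 px.",
          class = "meziq_error_validation")
  }
  band_depths_um <- as.list(band_depths_um)
  band_peak_values <- as.list(band_peak_values)
  if (!all(bands %in% names(band_depths_um)) ||
      !all(bands %in% names(band_peak_values)) ||
      !all(bands %in% names(band_sigma_um))) {
    abort(paste("Band parameters must name all of:",
                paste(bands, collapse = ", ")),
          class = "meziq_error_validation")
  }
  spec <- structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         lateral_scan_len_um = lateral_scan_len_um,
         axial_um_per_px = axial_um_per_px,
         band_depths_um = band_depths_um[bands],
         band_peak_values = band_peak_values[bands],
         band_sigma_um = band_sigma_um[bands],
         noise_sd = noise_sd, speckle_factor = speckle_factor,
         vessel_shadow_columns = vessel_shadow_columns,
         shadow_start_um = shadow_start_um,
         seed = as.integer(seed)),
    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

# Evaluate a depth/amplitude parameter at signed eccentricities u (um).
eval_lateral <- function(par, u) {
  if (is.function(par)) {
    v <- par(u)
  } else if (is.numeric(par)) {
    co <- c(par, 0, 0)[1:3]
    v <- co[1] + co[2] * u + co[3] * u^2
  } else {
    abort("Band parameter must be numeric or a function.",
          class = "meziq_error_validation")
  }
  rep_len(as.numeric(v), length(u))
}

validate_phantom_spec <- function(spec) {
  u <- seq(-spec$lateral_scan_len_um / 2, spec$lateral_scan_len_um / 2,
           length.out = 101)
  d <- lapply(spec$band_depths_um, eval_lateral, u = u)
  if (!all(d$inner_retina_complex < d$elm) || !all(d$elm < d$ez) ||
      !all(d$ez < d$rpe)) {
    abort(paste("Band depth ordering violated: inner retina < ELM < EZ < RPE",
                "must hold at every lateral position."),
          class = "meziq_error_validation")
  }
  amps <- lapply(spec$band_peak_values, eval_lateral, u = u)
  if (any(unlist(amps) <= 0)) {
    abort("All band peak values must be positive.",
          class = "meziq_error_validation")
  }
  if (any(unlist(spec$band_sigma_um) <= 0)) {
    abort("Band sigmas must be positive.", class = "meziq_error_validation")
  }
  for (sh in spec$vessel_shadow_columns) {
    if (length(sh) != 3 || sh[2] <= 0 || sh[3] <= 0 || sh[3] > 1) {
      abort(paste("Each vessel shadow must be c(center_um, width_um,",
                  "attenuation_fraction) with width > 0 and attenuation in",
                  "(0, 1]."), class = "meziq_error_validation")
    }
  }
  if (spec$noise_sd < 0 || spec$speckle_factor < 0) {
    abort("Noise parameters must be non-negative.",
          class = "meziq_error_validation")
  }
  invisible(spec)
}

#' Generate a synthetic B-scan with known ground truth
#'
#' Renders the noise-free band model of a [phantom_spec()] (the sum of the
#' per-band Gaussian axial profiles at every A-scan), then applies speckle,
#' additive noise and vessel shadows. The returned truth is computed from the
#' noise-free analytic amplitudes, not from the rendered raster: per sector,
#' the true mEZi is the maximum EZ amplitude over the sector's columns divided
#' by the maximum ELM amplitude (the max-over-columns semantics the
#' quantifier uses), and the global truth is the mean over non-shadowed
#' sectors.
#'
#' @param spec A [phantom_spec()].
#' @param n_sectors Number of ground-truth sectors tiling the analysis extent.
#' @param extent_um Analysis extent for the truth sectors, micrometres.
#' @param scale `"working"` returns the image on the post-log working scale
#'   (`is_log_transformed = TRUE`); `"linear"` inverts the log map so the
#'   image can be pushed through [log_transform()] end to end.
#' @param scan_id,meridian,scan_pos_um Passed to [bscan()].
#'
#' @return A list with elements `image` (a [bscan()]) and `truth` (class
#'   `phantom_truth`): `sectors` (tibble of `sector_id`, `center_um`,
#'   `true_mezi`, `shadowed`), `true_mezi` (global), `shadowed_sector_ids`,
#'   `band_depths_um`, `band_peak_values`, and `linear_max` (the linear-scale
#'   maximum when `scale = "linear"`).
#' @export
#' @examples
#' ph <- generate_bscan(phantom_spec(width_px = 128, height_px = 96))
#' ph$truth$true_mezi
generate_bscan <- function(spec, n_sectors = 220L, extent_um = 4000,
                           scale = c("working", "linear"),
                           scan_id = "phantom",
                           meridian = "horizontal", scan_pos_um = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  scale <- match.arg(scale)
  validate_phantom_spec(spec)

  px <- spec$lateral_scan_len_um / spec$width_px
  u <- (seq_len(spec$width_px) - 0.5) * px - spec$lateral_scan_len_um / 2
  z <- (seq_len(spec$height_px) - 0.5) * spec$axial_um_per_px

  depths <- lapply(spec$band_depths_um, eval_lateral, u = u)
  amps <- lapply(spec$band_peak_values, eval_lateral, u = u)

  clean <- matrix(0, spec$height_px, spec$width_px)
  for (b in names(depths)) {
    prof <- exp(-(outer(z, depths[[b]], "-"))^2 /
                  (2 * spec$band_sigma_um[[b]]^2))
    clean <- clean + sweep(prof, 2, amps[[b]], "*")
  }

  set.seed(spec$seed)
  img <- clean
  if (spec$speckle_factor > 0) {
    img <- img * matrix(rlnorm(length(img),
                               meanlog = -spec$speckle_factor^2 / 2,
                               sdlog = spec$speckle_factor),
                        nrow(img))
  }
  if (spec$noise_sd > 0) {
    img <- img + matrix(rnorm(length(img), sd = spec$noise_sd), nrow(img))
  }
  shadow_start <- spec$shadow_start_um %||%
    mean(c(mean(depths$inner_retina_complex), mean(depths$elm)))
  for (sh in spec$vessel_shadow_columns) {
    cols <- which(abs(u - sh[1]) <= sh[2] / 2)
    rows <- which(z >= shadow_start)
    if (length(cols) && length(rows)) {
      img[rows, cols] <- img[rows, cols] * (1 - sh[3])
    }
  }
  img <- pmax(img, 0)

  truth <- phantom_truth(spec, u, depths, amps, n_sectors, extent_um)

  linear_max <- NA_real_
  out <- bscan(img, lateral_um_per_px = px,
               axial_um_per_px = spec$axial_um_per_px,
               scan_id = scan_id, meridian = meridian,
               is_log_transformed = TRUE, scan_pos_um = scan_pos_um)
  if (scale == "linear") {
    # the rescaled log map preserves the image maximum, so the linear-scale
    # maximum equals the working-scale one and the round trip is exact
    linear_max <- max(out$pixels)
    out <- inverse_log_transform(out, original_max = linear_max)
  }
  truth$linear_max <- linear_max
  list(image = out, truth = truth)
}

phantom_truth <- function(spec, u, depths, amps, n_sectors, extent_um) {
  w <- extent_um / n_sectors
  edges <- -extent_um / 2 + w * (0:n_sectors)
  centers <- (head(edges, -1) + tail(edges, -1)) / 2
  shadows <- spec$vessel_shadow_columns

  sector <- map(seq_len(n_sectors), function(i) {
    in_bin <- u >= edges[i] & u < edges[i + 1]
    ratio <- if (any(in_bin)) {
      max(amps$ez[in_bin]) / max(amps$elm[in_bin])
    } else {
      # no rendered column falls in this bin; use analytic centre value
      eval_lateral(spec$band_peak_values$ez, centers[i]) /
        eval_lateral(spec$band_peak_values$elm, centers[i])
    }
    shadowed <- any(map_lgl(shadows, function(sh) {
      edges[i] < sh[1] + sh[2] / 2 && edges[i + 1] > sh[1] - sh[2] / 2
    }))
    tibble(sector_id = i, center_um = centers[i],
           true_mezi = ratio, shadowed = shadowed)
  })
  sectors <- bind_rows(sector)
  clear <- sectors$true_mezi[!sectors$shadowed]
  structure(
    list(sectors = sectors,
         true_mezi = if (length(clear)) mean(clear) else mean(sectors$true_mezi),
         shadowed_sector_ids = sectors$sector_id[sectors$shadowed],
         band_depths_um = spec$band_depths_um,
         band_peak_values = spec$band_peak_values),
    class = "phantom_truth")
}

#' Write phantom ground truth as a JSON sidecar
#'
#' @param truth A `phantom_truth` object from [generate_bscan()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_phantom_truth <- function(truth, path) {
  stopifnot(inherits(truth, "phantom_truth"))
  keep <- list(true_mezi = truth$true_mezi,
               shadowed_sector_ids = truth$shadowed_sector_ids,
               sectors = truth$sectors)
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate paired manual/automated mEZi measurements
#'
#' Emulates a three-group calibration design (normal, mild-to-moderate and
#' severe glaucoma): a latent true mEZi is drawn per eye from its group
#' distribution, the manual method (MM) observes it with additive noise, and
#' the automated method (AM) observes `method_slope * latent + method_bias`
#' with its own additive noise. With slope 1, bias 0 and zero noise the two
#' methods agree exactly row by row.
#'
#' @param n_per_group Eyes per group (scalar or length-3; each at least 2).
#' @param group_means,group_sds Length-3 latent means and SDs (SDs positive).
#' @param method_bias,method_slope Systematic offset and proportional error of
#'   the automated method relative to the latent truth.
#' @param noise_sd_each Measurement noise SD applied independently to each
#'   method (may be 0).
#' @param seed Integer RNG seed.
#' @param group_labels Labels for the three groups.
#'
#' @return A tibble with columns `unit_id`, `group`, `mm`, `am`.
#' @export
#' @examples
#' generate_paired_measurements(3, seed = 7)
generate_paired_measurements <- function(n_per_group = c(40L, 60L, 60L),
                                         group_means = c(4.08, 3.14, 2.36),
                                         group_sds = c(0.42, 0.43, 0.52),
                                         method_bias = 0,
                                         method_slope = 1,
                                         noise_sd_each = 0,
                                         seed = 1L,
                                         group_labels = c("normal",
                                                          "mild_to_moderate",
                                                          "severe")) {
  n_per_group <- rep_len(as.integer(n_per_group), 3L)
  if (any(n_per_group < 2)) {
    abort("`n_per_group` must be at least 2 per group.",
          class = "meziq_error_validation")
  }
  if (length(group_means) != 3 || length(group_sds) != 3 ||
      any(group_sds <= 0)) {
    abort("`group_means` and `group_sds` must have length 3 with positive SDs.",
          class = "meziq_error_validation")
  }
  if (noise_sd_each < 0) {
    abort("`noise_sd_each` must be non-negative.",
          class = "meziq_error_validation")
  }
  set.seed(seed)
  grp <- rep(group_labels, times = n_per_group)
  latent <- rnorm(sum(n_per_group),
                  mean = rep(group_means, times = n_per_group),
                  sd = rep(group_sds, times = n_per_group))
  mm <- latent + rnorm(length(latent), sd = noise_sd_each)
  am <- method_slope * latent + method_bias +
    rnorm(length(latent), sd = noise_sd_each)
  tibble(unit_id = sprintf("eye%03d", seq_along(latent)),
         group = factor(grp, levels = group_labels),
         mm = mm, am = am)
}

#' Write a paired-measurement table as CSV
#'
#' Header is `unit_id,group,mm,am`.
#'
#' @param data Tibble from [generate_paired_measurements()].
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_paired_csv <- function(data, path) {
  write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Read a paired-measurement CSV
#'
#' Accepts the `unit_id,group,mm,am` schema (or `group,mm,am`; unit ids are
#' then synthesised).
#'
#' @param path CSV path.
#' @return A tibble with columns `unit_id`, `group`, `mm`, `am`.
#' @export
read_paired_csv <- function(path) {
  d <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("mm", "am") %in% names(d))) {
    abort("Paired CSV must contain columns `mm` and `am`.",
          class = "meziq_error_io")
  }
  if (!"unit_id" %in% names(d)) {
    d$unit_id <- sprintf("eye%03d", seq_len(nrow(d)))
  }
  if (!"group" %in% names(d)) d$group <- "unknown"
  bad <- which(!complete.cases(d[, c("mm", "am")]))
  if (length(bad)) {
    abort(sprintf("Missing mm/am value at row %d.", bad[1]),
          class = "meziq_error_io")
  }
  d[, c("unit_id", "group", "mm", "am")]
}
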