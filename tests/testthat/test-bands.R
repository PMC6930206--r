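test_that("Otsu threshold agrees with an independent implementation", {
  skip_if_not_installed("EBImage")
  set.seed(12)
  m <- matrix(c(rnorm(4000, 30, 8), rnorm(1000, 180, 20)), 50)
  m <- pmax(m, 0)
  mine <- otsu_threshold(m, n_bins = 256L)
  ref <- EBImage::otsu(EBImage::Image(m / max(m)), range = c(0, 1),
                       levels = 256) * max(m)
  bin_width <- diff(range(m)) / 256
  expect_lt(abs(mine - ref), 2 * bin_width)
})

test_that("inner retina is eliminated while the outer complex is retained", {
  spec <- quick_spec(band_depths_um = list(
    inner_retina_complex = 100, elm = 250, ez = 290, rpe = 340),
    band_peak_values = c(inner_retina_complex = 200, elm = 60, ez = 240,
                         rpe = 255))
  ph <- generate_bscan(spec)
  img <- crop_central_region(ph$image, extent_um = 4000)
  elim <- eliminate_inner_retina(img)
  expect_false(elim$failed)
  axpx <- img$axial_um_per_px
  retained_um <- c(elim$crop_window[["row_lo"]] - 1,
                   elim$crop_window[["row_hi"]]) * axpx
  expect_gt(retained_um[1], 100)   # inner band depth excluded
  expect_lt(retained_um[1], 250)   # ELM depth retained
  expect_gt(retained_um[2], 340)   # RPE depth retained
  # every column keeps zero signal at the inner band depth
  inner_row <- round(100 / axpx)
  expect_true(all(elim$image$pixels[inner_row, ] == 0))
})

test_that("elimination is idempotent and a no-op without an inner retina", {
  ph <- generate_bscan(quick_spec())
  img <- crop_central_region(ph$image, extent_um = 4000)
  e1 <- eliminate_inner_retina(img)
  e2 <- eliminate_inner_retina(e1$image)
  expect_identical(e2$image$pixels, e1$image$pixels)
  expect_identical(e2$crop_window, e1$crop_window)

  tiny <- function(u) 1e-9  # effectively no inner retina
  spec <- quick_spec(band_peak_values = list(
    inner_retina_complex = tiny, elm = 60, ez = 240, rpe = 255))
  ph2 <- generate_bscan(spec)
  img2 <- crop_central_region(ph2$image, extent_um = 4000)
  e3 <- eliminate_inner_retina(img2)
  outer_rows <- round(c(245, 340) / img2$axial_um_per_px)
  expect_equal(e3$image$pixels[outer_rows[1]:outer_rows[2], ],
               img2$pixels[outer_rows[1]:outer_rows[2], ])
})

test_that("all-zero input takes the failure path", {
  z <- bscan(matrix(0, 96, 256), 17.6, 3.87, is_log_transformed = TRUE)
  elim <- eliminate_inner_retina(z)
  expect_true(elim$failed)
  ex <- extract_bands(elim$image, elim$crop_window)
  expect_true(ex$failed)
  expect_true(detect_failure(ex))
})

test_that("extracted peaks match configured amplitudes and depths", {
  res <- quick_extraction()
  ex <- res$extraction
  ok <- ex$columns$valid
  expect_gt(mean(ok), 0.99)
  expect_true(all(abs(ex$columns$elm_peak[ok] - 60) / 60 < 0.02))
  expect_true(all(abs(ex$columns$ez_peak[ok] - 240) / 240 < 0.02))
  axpx <- ex$axial_um_per_px
  # depths within one pixel of the configured band centres
  expect_true(all(abs((ex$columns$elm_depth_px[ok] - 0.5) * axpx - 250) <= axpx))
  # EZ sits at 290 um; the RPE at 340 um must never be picked as EZ
  expect_true(all(abs((ex$columns$ez_depth_px[ok] - 0.5) * axpx - 290) <= axpx))
  # ordering invariant
  expect_true(all(ex$columns$elm_depth_px[ok] < ex$columns$ez_depth_px[ok]))
  expect_true(all(ex$columns$elm_peak[ok] > 0 & ex$columns$ez_peak[ok] > 0))
})

test_that("a column with a single band cannot form a ratio", {
  h <- 100; w <- 64
  z <- (seq_len(h) - 0.5) * 4
  one_band <- 200 * exp(-(z - 250)^2 / (2 * 8^2))
  img <- bscan(matrix(one_band, h, w), 17.6, 4, is_log_transformed = TRUE)
  elim <- eliminate_inner_retina(img)
  ex <- extract_bands(elim$image, elim$crop_window)
  expect_true(all(!ex$columns$valid))
  expect_true(all(ex$columns$reason == "no_valid_peak"))
  expect_true(ex$failed)
})

test_that("vessel shadows are excluded and clean columns retained", {
  spec <- quick_spec(vessel_shadow_columns = list(c(-500, 100, 0.9)))
  ph <- generate_bscan(spec)
  ex <- quantify_bscan(ph$image, extent_um = 4000)
  px <- ex$lateral_um_per_px
  shadow_cols <- which(abs(ex$columns$lateral_um + 500) <= 50)
  clean_cols <- which(abs(ex$columns$lateral_um + 500) > 50 + 2 * px)
  expect_gte(mean(!ex$columns$valid[shadow_cols]), 0.95)
  expect_gte(mean(ex$columns$valid[clean_cols]), 0.95)
  expect_true(all(ex$columns$reason[shadow_cols] == "vessel_shadow"))
})

test_that("a shadow-free noise-free phantom loses no columns to shadows", {
  ph <- generate_bscan(quick_spec())
  ex <- quantify_bscan(ph$image, extent_um = 4000)
  expect_false(any(ex$columns$reason == "vessel_shadow"))
})

test_that("two disjoint shadows yield two disjoint invalid runs", {
  spec <- quick_spec(vessel_shadow_columns = list(c(-800, 120, 0.9),
                                                  c(700, 120, 0.9)))
  ph <- generate_bscan(spec)
  ex <- quantify_bscan(ph$image, extent_um = 4000)
  r <- rle(ex$columns$reason == "vessel_shadow")
  expect_equal(sum(r$values), 2)
})

test_that("flat scans pass and curved-off-frame scans fail detection", {
  flat <- quick_extraction()$extraction
  expect_false(flat$failed)
  expect_false(detect_failure(flat))

  # bands leave the bottom of the frame for well over half of the columns
  c2 <- 2.6e-3
  spec <- phantom_spec(band_depths_um = list(
    inner_retina_complex = c(120, 0, c2 / 4), elm = c(250, 0, c2),
    ez = c(290, 0, c2), rpe = c(340, 0, c2)))
  ph <- generate_bscan(spec)
  ex <- quantify_bscan(ph$image)
  expect_true(ex$failed)
  expect_error(am_quantify_scan(ex), class = "meziq_error_failed_scan")
})
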