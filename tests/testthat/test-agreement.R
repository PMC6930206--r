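test_that("Deming regression reproduces exact lines", {
  d <- tibble::tibble(mm = c(1, 2, 3), am = c(3, 5, 7))
  fit <- deming_fit(d, jackknife = FALSE)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)

  d2 <- tibble::tibble(mm = c(0, 1, 0.5), am = c(1, 0, 0.5))
  fit2 <- deming_fit(d2, jackknife = FALSE)
  expect_equal(fit2$slope, -1)
  expect_equal(fit2$intercept, 1)
})

test_that("Deming line passes through the centroid", {
  set.seed(14)
  d <- tibble::tibble(mm = rnorm(50, 3), am = rnorm(50, 3) + rnorm(50, 0, .2))
  d$am <- 1.2 * d$mm + 0.3 + rnorm(50, 0, 0.3)
  fit <- deming_fit(d)
  expect_lt(abs(mean(d$am) - (fit$intercept + fit$slope * mean(d$mm))), 1e-10)
})

test_that("closed-form Deming matches the grid-search oracle", {
  set.seed(77)
  for (i in 1:5) {
    n <- sample(50:200, 1)
    x <- rnorm(n, 3, 0.8)
    y <- runif(1, 0.6, 1.6) * x + runif(1, -1, 1) + rnorm(n, 0, 0.3)
    d <- tibble::tibble(mm = x, am = y)
    fit <- deming_fit(d, jackknife = FALSE)
    oracle <- deming_grid_oracle(x, y)
    expect_lt(abs(fit$slope - oracle["slope"]), 1e-6)
    expect_lt(abs(fit$intercept - oracle["intercept"]), 1e-6)
  }
})

test_that("Deming limits and symmetries behave as theory says", {
  set.seed(15)
  x <- rnorm(80, 3, 0.7)
  y <- 1.3 * x - 0.4 + rnorm(80, 0, 0.25)
  d <- tibble::tibble(mm = x, am = y)
  # lambda -> Inf approaches OLS of y on x
  big <- deming_fit(d, lambda = 1e9, jackknife = FALSE)
  ols <- coef(lm(y ~ x))
  expect_equal(big$slope, unname(ols[2]), tolerance = 1e-5)
  expect_equal(big$intercept, unname(ols[1]), tolerance = 1e-4)
  # axis swap at lambda = 1 inverts the line
  fwd <- deming_fit(d, jackknife = FALSE)
  rev <- deming_fit(tibble::tibble(mm = y, am = x), jackknife = FALSE)
  expect_equal(rev$slope, 1 / fwd$slope, tolerance = 1e-10)
  # R^2 symmetric in x and y
  expect_equal(fwd$r_squared, rev$r_squared)
})

test_that("degenerate Deming inputs are rejected", {
  expect_error(deming_fit(tibble::tibble(mm = c(1, 2), am = c(1, 2))),
               class = "meziq_error_validation")
  expect_error(
    deming_fit(tibble::tibble(mm = c(1, 1, 1), am = c(1, 2, 3))),
    class = "meziq_error_validation")
  expect_error(
    deming_fit(tibble::tibble(mm = c(1, 2, 3), am = c(2, 2, 2))),
    class = "meziq_error_validation")
})

test_that("jackknife recovers a generating line within 3 SEs", {
  d <- generate_paired_measurements(c(40, 60, 60), method_slope = 1.047,
                                    method_bias = -0.058,
                                    noise_sd_each = 0.242, seed = 42)
  fit <- deming_fit(d)
  expect_lt(abs(fit$slope - 1.047), 3 * fit$se_slope)
  expect_lt(abs(fit$intercept - (-0.058)), 3 * fit$se_intercept)
})

test_that("Bland-Altman statistics match hand computations", {
  d <- tibble::tibble(mm = c(1, 2, 3, 4), am = c(1.5, 2.5, 3.5, 4.5))
  ba <- bland_altman(d)
  expect_equal(ba$mean_diff, 0.5)
  expect_equal(ba$sd_diff, 0)
  expect_equal(c(ba$loa_lo, ba$loa_hi), c(0.5, 0.5))

  d2 <- tibble::tibble(mm = c(2, 2), am = c(1, 3))  # diffs -1, +1
  ba2 <- bland_altman(d2)
  expect_equal(ba2$mean_diff, 0)
  expect_equal(ba2$sd_diff, sqrt(2))
  expect_equal(ba2$loa_hi, 1.96 * sqrt(2))
  # limits reconstruct exactly from mean and SD
  expect_equal(ba2$loa_hi - ba2$loa_lo, 2 * 1.96 * ba2$sd_diff,
               tolerance = 1e-10)

  expect_error(bland_altman(tibble::tibble(mm = 1, am = 2)),
               class = "meziq_error_validation")
})

test_that("emulated calibration reproduces the printed agreement geometry", {
  d <- generate_paired_measurements(c(40, 60, 60), method_slope = 1.047,
                                    method_bias = -0.058,
                                    noise_sd_each = 0.242, seed = 42)
  ba <- bland_altman(d)
  # expected mean difference: (slope-1)*E[latent] + bias = 0.087
  expect_lt(abs(ba$mean_diff - 0.09), 0.1)
  expect_lt(abs(ba$loa_lo - (-0.59)), 0.1)
  expect_lt(abs(ba$loa_hi - 0.76), 0.1)
})

test_that("compensation fits the difference-vs-average line", {
  x <- seq(1, 5, length.out = 20)
  d <- tibble::tibble(mm = x, am = x + 0.2)
  comp <- fit_compensation(d)
  expect_equal(comp$a, 0.2, tolerance = 1e-12)
  expect_equal(comp$b, 0, tolerance = 1e-12)
  expect_equal(apply_compensation(comp, 3.0), 2.8)

  ident <- fit_compensation(tibble::tibble(mm = x, am = x))
  expect_equal(c(ident$a, ident$b), c(0, 0), tolerance = 1e-12)
  expect_equal(apply_compensation(ident, x), x)

  prop <- fit_compensation(tibble::tibble(mm = x, am = 1.1 * x))
  expect_gt(prop$b, 0)
})

test_that("compensating the calibration set is an exact fixed point", {
  set.seed(23)
  x <- rnorm(60, 3, 0.7)
  y <- 1.1 * x - 0.2 + rnorm(60, 0, 0.2)
  d <- tibble::tibble(mm = x, am = y)
  comp <- fit_compensation(d)
  amc <- apply_compensation(comp, d$am, avg = (d$mm + d$am) / 2)
  refit <- fit_compensation(tibble::tibble(mm = d$mm, am = amc))
  expect_lt(abs(refit$a), 1e-8)
  expect_lt(abs(refit$b), 1e-8)
})

test_that("lone-value compensation straightens a proportional bias", {
  set.seed(24)
  x <- rnorm(100, 3, 0.7)
  d <- tibble::tibble(mm = x, am = 1.1 * x)
  comp <- fit_compensation(d)
  amc <- apply_compensation(comp, d$am)
  fit <- deming_fit(tibble::tibble(mm = x, am = amc), jackknife = FALSE)
  expect_equal(fit$slope, 1, tolerance = 0.02)
  expect_equal(fit$intercept, 0, tolerance = 0.02)
})

test_that("replicate confidence intervals follow the t distribution", {
  same <- replicate_ci(rep(3.1, 5))
  expect_equal(c(same$mean, same$ci_lo, same$ci_hi), c(3.1, 3.1, 3.1))

  ci <- replicate_ci(1:5)
  half <- qt(0.975, 4) * sd(1:5) / sqrt(5)
  expect_equal(ci$mean, 3)
  expect_equal(ci$ci_hi - ci$mean, half)
  expect_true(ci$ci_lo <= ci$mean & ci$mean <= ci$ci_hi)

  wide <- replicate_ci(c(1, 3, 5, 7, 9))
  expect_gt(wide$ci_hi - wide$ci_lo, ci$ci_hi - ci$ci_lo)

  expect_error(replicate_ci(3), class = "meziq_error_validation")
})

test_that("coverage counts closed-interval membership by unit", {
  cis <- tibble::tibble(unit_id = paste0("u", 1:10),
                        ci_lo = 1:10 - 0.5, ci_hi = 1:10 + 0.5)
  am <- tibble::tibble(unit_id = paste0("u", 1:10), value = as.numeric(1:10))
  cov <- ci_coverage(am, cis)
  expect_equal(cov$fraction, 1)

  am$value[4] <- 4.51  # just outside the closed interval
  cov2 <- ci_coverage(am, cis)
  expect_equal(cov2$n_inside, 9L)
  # boundary value is inside (closed interval)
  am$value[4] <- 4.5
  expect_equal(ci_coverage(am, cis)$n_inside, 10L)

  am$unit_id[1] <- "other"
  expect_error(ci_coverage(am, cis), class = "meziq_error_validation")
})

test_that("rank-sum test is exact for small groups and consistent for large", {
  same <- rank_sum_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  sep <- rank_sum_compare(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$U, 0)
  expect_equal(sep$p_value, 0.1)

  # oracle: wilcox.test exact p on untied small samples
  set.seed(9)
  a <- runif(6); b <- runif(7) + 0.3
  mine <- rank_sum_compare(a, b)
  ref <- wilcox.test(a, b, exact = TRUE)
  expect_equal(mine$p_value, ref$p.value)
  expect_equal(mine$U, unname(ref$statistic))

  # large samples: p shrinks monotonically with the shift
  set.seed(10)
  base <- rnorm(30)
  ps <- vapply(c(0.2, 0.6, 1.2),
               function(s) rank_sum_compare(base, base + s)$p_value,
               numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_lt(ps[3], 0.001)

  expect_error(rank_sum_compare(numeric(0), 1:3),
               class = "meziq_error_validation")
})

test_that("agreement objects expose tidy, glance and autoplot", {
  d <- generate_paired_measurements(10, noise_sd_each = 0.1, seed = 2)
  fit <- deming_fit(d)
  expect_named(tidy(fit), c("term", "estimate", "std.error"))
  expect_equal(glance(fit)$nobs, 30)
  expect_s3_class(autoplot(fit), "ggplot")
  ba <- bland_altman(d)
  expect_true(all(c("mean_diff", "loa_lo") %in% tidy(ba)$term))
  expect_s3_class(autoplot(ba), "ggplot")
})
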