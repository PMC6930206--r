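#' Deming errors-in-variables regression
#'
#' Fits the line minimising the sum of squared distances measured obliquely
#' according to the error-variance ratio `lambda = var(e_y)/var(e_x)`
#' (orthogonal distances when `lambda = 1`, the default). Unlike ordinary
#' least squares, both variables are treated as measured with error — the
#' appropriate model when comparing two measurement methods. The closed form
#' is
#' \deqn{b = \frac{s_{yy} - \lambda s_{xx} +
#'   \sqrt{(s_{yy}-\lambda s_{xx})^2 + 4\lambda s_{xy}^2}}{2 s_{xy}},
#'   \quad a = \bar y - b\,\bar x.}
#' The reported `r_squared` is the squared Pearson correlation of x and y
#' (Deming regression has no canonical R-squared). Standard errors are
#' leave-one-out jackknife estimates.
#'
#' @param data Data frame of paired measurements.
#' @param lambda Ratio of the y- to x-error variances.
#' @param x,y Column names of the reference (manual) and test (automated)
#'   measurements.
#' @param jackknife Compute jackknife standard errors (default `TRUE`).
#' @return An object of class `deming_fit` with elements `slope`,
#'   `intercept`, `r_squared`, `lambda`, `n`, `se_slope`, `se_intercept`,
#'   and the fitted data.
#' @export
#' @examples
#' d <- tibble::tibble(mm = 1:5, am = 2 * (1:5) + 1)
#' deming_fit(d)
deming_fit <- function(data, lambda = 1, x = "mm", y = "am",
                       jackknife = TRUE) {
  xv <- pull_numeric(data, x)
  yv <- pull_numeric(data, y)
  n <- length(xv)
  if (n < 3) {
    abort("Deming regression needs at least 3 pairs.",
          class = "meziq_error_validation")
  }
  if (lambda <= 0) {
    abort("`lambda` must be positive.", class = "meziq_error_validation")
  }
  est <- deming_coef(xv, yv, lambda)
  se <- c(NA_real_, NA_real_)
  if (jackknife && n > 3) {
    loo <- vapply(seq_len(n),
                  function(i) deming_coef(xv[-i], yv[-i], lambda),
                  numeric(2))
    se <- sqrt((n - 1) / n * rowSums((loo - rowMeans(loo))^2))
  }
  structure(
    list(slope = est[[1]], intercept = est[[2]],
         r_squared = cor(xv, yv)^2, lambda = lambda, n = n,
         se_slope = se[1], se_intercept = se[2],
         x = x, y = y, data = tibble(x = xv, y = yv)),
    class = "deming_fit")
}

deming_coef <- function(xv, yv, lambda) {
  if (var(xv) == 0) {
    abort("x has zero variance; the line is vertical.",
          class = "meziq_error_validation")
  }
  sxx <- var(xv); syy <- var(yv); sxy <- cov(xv, yv)
  if (sxy == 0) {
    abort("x and y are uncorrelated; the Deming line is undefined.",
          class = "meziq_error_validation")
  }
  d <- syy - lambda * sxx
  slope <- (d + sqrt(d^2 + 4 * lambda * sxy^2)) / (2 * sxy)
  c(slope = slope, intercept = mean(yv) - slope * mean(xv))
}

pull_numeric <- function(data, col) {
  if (!is.data.frame(data) || !col %in% names(data)) {
    abort(sprintf("`data` must contain a numeric column '%s'.", col),
          class = "meziq_error_validation")
  }
  v <- data[[col]]
  if (!is.numeric(v) || anyNA(v)) {
    abort(sprintf("Column '%s' must be numeric with no missing values.", col),
          class = "meziq_error_validation")
  }
  v
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf(
    "Deming regression (lambda = %g, n = %d)\n  %s = %.4f(%s) %+.4f,  R^2 = %.4f\n",
    x$lambda, x$n, x$y, x$slope, x$x, x$intercept, x$r_squared))
  invisible(x)
}

#' @rdname deming_fit
#' @param x A `deming_fit`.
#' @param ... Unused.
#' @export
tidy.deming_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = c(x$se_intercept, x$se_slope))
}

#' @rdname deming_fit
#' @export
glance.deming_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, lambda = x$lambda, nobs = x$n)
}

#' @rdname deming_fit
#' @param object A `deming_fit`.
#' @export
autoplot.deming_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = paste(object$x, "mEZi"), y = paste(object$y, "mEZi"),
      title = sprintf("%s = %.3f(%s) %+.3f, R² = %.3f",
                      object$y, object$slope, object$x, object$intercept,
                      object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Bland-Altman agreement analysis
#'
#' Computes per-pair differences `d = y - x` (automated minus manual), their
#' mean and sample SD, the 95% limits of agreement `mean +/- 1.96 SD`, and
#' the ordinary least-squares regression of the difference on the pair
#' average, which quantifies any proportional trend in the disagreement.
#'
#' @inheritParams deming_fit
#' @param conf_mult Multiplier on the SD for the limits (1.96 for 95%).
#' @return An object of class `bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa_lo`, `loa_hi`, `diff_vs_avg_intercept`, `diff_vs_avg_slope`, `n`.
#' @export
bland_altman <- function(data, x = "mm", y = "am", conf_mult = 1.96) {
  xv <- pull_numeric(data, x)
  yv <- pull_numeric(data, y)
  n <- length(xv)
  if (n < 2) {
    abort("Bland-Altman needs at least 2 pairs.",
          class = "meziq_error_validation")
  }
  d <- yv - xv
  avg <- (xv + yv) / 2
  m <- mean(d); s <- sd(d)
  co <- if (var(avg) > 0) coef(lm(d ~ avg)) else c(m, NA_real_)
  structure(
    list(mean_diff = m, sd_diff = s,
         loa_lo = m - conf_mult * s, loa_hi = m + conf_mult * s,
         diff_vs_avg_intercept = unname(co[1]),
         diff_vs_avg_slope = unname(co[2]),
         conf_mult = conf_mult, n = n, x = x, y = y,
         data = tibble(avg = avg, diff = d)),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): mean diff %.4f, SD %.4f, LoA [%.4f, %.4f]\n",
    x$n, x$mean_diff, x$sd_diff, x$loa_lo, x$loa_hi))
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `bland_altman`.
#' @param ... Unused.
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble(term = c("mean_diff", "sd_diff", "loa_lo", "loa_hi",
                  "diff_vs_avg_intercept", "diff_vs_avg_slope"),
         estimate = c(x$mean_diff, x$sd_diff, x$loa_lo, x$loa_hi,
                      x$diff_vs_avg_intercept, x$diff_vs_avg_slope))
}

#' @rdname bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble(mean_diff = x$mean_diff, sd_diff = x$sd_diff,
         loa_lo = x$loa_lo, loa_hi = x$loa_hi, nobs = x$n)
}

#' @rdname bland_altman
#' @param object A `bland_altman`.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$mean_diff, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_lo, object$loa_hi),
                        colour = "firebrick", linetype = "dashed") +
    ggplot2::labs(x = sprintf("Average of %s and %s", object$x, object$y),
                  y = sprintf("%s - %s", object$y, object$x),
                  title = sprintf("Mean diff %.3f, LoA [%.3f, %.3f]",
                                  object$mean_diff, object$loa_lo,
                                  object$loa_hi)) +
    ggplot2::theme_minimal()
}

#' Fit the difference-versus-average compensation model
#'
#' Regresses the between-method difference `y - x` on the pair average
#' `(x + y)/2` by ordinary least squares over the calibration set. The
#' fitted `(a, b)` are later used by [apply_compensation()] to correct
#' automated measurements toward the manual scale.
#'
#' @inheritParams deming_fit
#' @return An object of class `compensation_model` with elements `a`
#'   (intercept), `b` (slope) and `n`.
#' @export
fit_compensation <- function(data, x = "mm", y = "am") {
  xv <- pull_numeric(data, x)
  yv <- pull_numeric(data, y)
  if (length(xv) < 3) {
    abort("Compensation fit needs at least 3 pairs.",
          class = "meziq_error_validation")
  }
  avg <- (xv + yv) / 2
  if (var(avg) == 0) {
    abort("Pair averages are constant; the compensation line is undefined.",
          class = "meziq_error_validation")
  }
  co <- coef(lm((yv - xv) ~ avg))
  structure(list(a = unname(co[1]), b = unname(co[2]), n = length(xv)),
            class = "compensation_model")
}

#' @export
print.compensation_model <- function(x, ...) {
  cat(sprintf("Compensation model (n = %d): diff = %.4f %+.4f * average\n",
              x$n, x$a, x$b))
  invisible(x)
}

#' Apply a compensation model to automated measurements
#'
#' Subtracts the modelled disagreement from an automated value:
#' `am - (a + b * avg)`. When the pair average is available (paired data) it
#' is used directly, which makes compensation of the calibration set an
#' exact fixed point — the refitted difference-versus-average coefficients
#' are identically zero, because least-squares residuals are orthogonal to
#' any affine transform of the regressor. For a lone automated value (the
#' validation setting, where no trusted average exists) the AM value stands
#' in for the average: `am - (a + b * am)`; with `b = 0` both forms reduce
#' to subtracting the mean bias.
#'
#' @param model A `compensation_model`.
#' @param am Numeric vector of automated measurements.
#' @param avg Optional matching pair averages.
#' @return Compensated values, same length as `am`.
#' @export
apply_compensation <- function(model, am, avg = NULL) {
  stopifnot(inherits(model, "compensation_model"))
  ref <- avg %||% am
  if (length(ref) != length(am)) {
    abort("`avg` must match `am` in length.",
          class = "meziq_error_validation")
  }
  am - (model$a + model$b * ref)
}

#' Replicate mean and 95% confidence interval
#'
#' A t-based two-sided confidence interval for the mean of `k` repeated
#' quantifications of one image (df = k - 1; k = 5 in the validation
#' design).
#'
#' @param replicates Numeric vector of repeated measurements (length >= 2).
#' @param conf Confidence level.
#' @return A one-row tibble: `mean`, `ci_lo`, `ci_hi`, `k`.
#' @export
#' @examples
#' replicate_ci(c(1, 2, 3, 4, 5))
replicate_ci <- function(replicates, conf = 0.95) {
  k <- length(replicates)
  if (k < 2 || anyNA(replicates)) {
    abort("Need at least 2 non-missing replicates.",
          class = "meziq_error_validation")
  }
  m <- mean(replicates)
  half <- qt(1 - (1 - conf) / 2, df = k - 1) * sd(replicates) / sqrt(k)
  tibble(mean = m, ci_lo = m - half, ci_hi = m + half, k = k)
}

#' Coverage of replicate confidence intervals by compensated AM values
#'
#' Counts the units whose compensated automated value lies inside the closed
#' replicate confidence interval of the manual method.
#'
#' @param am Tibble with columns `unit_id` and `value` (compensated AM), or a
#'   named numeric vector.
#' @param cis Tibble with columns `unit_id`, `ci_lo`, `ci_hi` (e.g. from
#'   [replicate_ci()] applied per unit).
#' @return A list: `n_inside`, `n`, `fraction`.
#' @export
ci_coverage <- function(am, cis) {
  if (is.numeric(am)) {
    am <- tibble(unit_id = names(am) %||% as.character(seq_along(am)),
                 value = unname(am))
  }
  if (!all(c("unit_id", "value") %in% names(am)) ||
      !all(c("unit_id", "ci_lo", "ci_hi") %in% names(cis))) {
    abort("`am` needs unit_id/value; `cis` needs unit_id/ci_lo/ci_hi.",
          class = "meziq_error_validation")
  }
  if (!setequal(am$unit_id, cis$unit_id)) {
    abort("Unit ids of `am` and `cis` do not match.",
          class = "meziq_error_validation")
  }
  j <- left_join(am, cis, by = "unit_id")
  if (nrow(j) == 0) {
    abort("No overlapping units.", class = "meziq_error_validation")
  }
  inside <- j$value >= j$ci_lo & j$value <= j$ci_hi
  list(n_inside = sum(inside), n = nrow(j), fraction = mean(inside))
}

#' Mann-Whitney rank-sum comparison of two groups
#'
#' Two-sided Mann-Whitney U test. For small samples (both groups under
#' `exact_max`) the p-value is computed by exact enumeration of all group
#' assignments using midranks, so ties are handled exactly; for larger
#' samples the tie-corrected normal approximation with continuity correction
#' is used.
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @param exact_max Exact enumeration is used when both groups are smaller
#'   than this.
#' @return A list: `U` (statistic for `group_a`), `p_value`, `method`.
#' @export
rank_sum_compare <- function(group_a, group_b, exact_max = 8L) {
  n <- length(group_a); m <- length(group_b)
  if (n == 0 || m == 0) {
    abort("Both groups must be non-empty.", class = "meziq_error_validation")
  }
  pooled <- c(group_a, group_b)
  rk <- rank(pooled)  # midranks
  U <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  if (n < exact_max && m < exact_max) {
    idx <- utils::combn(n + m, n)
    Us <- colSums(matrix(rk[idx], nrow = n)) - n * (n + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
    method <- "exact enumeration (midranks)"
  } else {
    N <- n + m
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(n * m / 12 * (N + 1 - tie_term))
    z <- (abs(U - mu) - 0.5) / sigma
    p <- min(1, 2 * pnorm(z, lower.tail = FALSE))
    method <- "normal approximation (tie-corrected)"
  }
  list(U = U, p_value = p, method = method)
}
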