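#' Construct a resolution curve from known parameters
#'
#' A resolution curve is the power law \eqn{R(m/z) = C \cdot (m/z)^k} relating
#' Orbitrap resolving power (\eqn{m/\Delta m} at FWHM) to m/z. On Orbitrap
#' analyzers the exponent is close to \eqn{k = -0.5}: resolving power decays
#' with the square root of m/z, so absolute peak widths (and hence sensible
#' bin widths) grow as \eqn{(m/z)^{1.5}}.
#'
#' @param coefficient Positive scale factor \eqn{C} of the power law.
#' @param index Exponent \eqn{k}; negative for Orbitrap data.
#' @param n_points Number of points the curve was fitted on (0 for a curve
#'   constructed from nominal instrument settings).
#' @param r_squared Coefficient of determination of the fit (`NA` when the
#'   curve was not fitted).
#'
#' @return An object of class `resolution_curve`.
#' @seealso [orbitrap_curve()] for the common "resolution at m/z 200"
#'   parameterization, [fit_resolution_curve()] to estimate the parameters
#'   from data.
#' @export
#' @examples
#' curve <- resolution_curve(coefficient = 989949.49, index = -0.5)
#' predict_resolution(curve, 200) # ~70,000
resolution_curve <- function(coefficient, index, n_points = 0L, r_squared = NA_real_) {
  check_number(coefficient, "coefficient")
  if (!is.numeric(index) || length(index) != 1L || is.na(index)) {
    stop_validation("`index` must be a finite numeric scalar.")
  }
  if (!is.na(r_squared) && r_squared > 1 + 1e-12) {
    stop_validation("`r_squared` cannot exceed 1.")
  }
  structure(
    list(coefficient = as.numeric(coefficient), index = as.numeric(index),
         n_points = as.integer(n_points), r_squared = as.numeric(r_squared)),
    class = "resolution_curve"
  )
}

#' Resolution curve anchored at a reference m/z
#'
#' Orbitrap instrument settings quote resolving power at a reference m/z
#' (conventionally 200, e.g. "70,000 at m/z 200"). This helper converts that
#' setting into a [resolution_curve()]: \eqn{C = R_{ref} / m_{ref}^k}.
#'
#' @param resolution Resolving power at `at_mz`.
#' @param at_mz Reference m/z (default 200).
#' @param index Power-law exponent (default -0.5, the Orbitrap value).
#' @return A `resolution_curve`.
#' @export
#' @examples
#' orbitrap_curve(70000)          # Q Exactive full-scan setting
#' orbitrap_curve(60000)          # Orbitrap Exploris 120 setting
orbitrap_curve <- function(resolution, at_mz = 200, index = -0.5) {
  check_number(resolution, "resolution")
  check_number(at_mz, "at_mz")
  resolution_curve(coefficient = resolution / at_mz^index, index = index)
}

#' Fit the resolution--m/z power law
#'
#' Estimates \eqn{C} and \eqn{k} in \eqn{R = C \cdot (m/z)^k} by nonlinear
#' least squares on the linear (resolution) scale. A log--log linear
#' regression supplies the starting values, then Levenberg--Marquardt
#' refinement ([minpack.lm::nlsLM()]) minimizes the residual sum of squares
#' of \eqn{R - C m^k} directly, so high-resolution points are not
#' down-weighted the way a pure log-space fit would. \eqn{R^2} is reported on
#' the linear scale.
#'
#' @param points Data frame with columns `mz` and `resolution`, one row per
#'   observed (m/z, resolving power) pair; at least 3 rows, all positive.
#' @return A `resolution_curve` with `n_points` and `r_squared` filled in and
#'   the input retained (for [autoplot()]).
#' @export
#' @examples
#' pts <- simulate_resolution_points(orbitrap_curve(70000), n = 50,
#'                                   rel_noise = 0, seed = 1)
#' fit <- fit_resolution_curve(pts)
#' glance(fit)
fit_resolution_curve <- function(points) {
  check_columns(points, c("mz", "resolution"), "points")
  if (nrow(points) < 3L) {
    stop_degenerate(sprintf(
      "Need at least 3 (mz, resolution) points to fit a two-parameter curve; got %d.",
      nrow(points)))
  }
  mz <- as.numeric(points$mz)
  res <- as.numeric(points$resolution)
  if (anyNA(mz) || anyNA(res) || any(mz <= 0) || any(res <= 0)) {
    stop_validation("All `mz` and `resolution` values must be positive and non-missing.")
  }

  # log-log linear regression gives a robust starting point without any
  # user-supplied guess; the LM refinement then works on the linear scale
  init <- lm(log(res) ~ log(mz))
  start <- list(C = exp(coef(init)[[1]]), k = coef(init)[[2]])

  fit <- tryCatch(
    minpack.lm::nlsLM(
      res ~ C * mz^k,
      start = start,
      control = minpack.lm::nls.lm.control(ftol = 1e-10, maxiter = 500)
    ),
    error = function(e) {
      stop_fit(sprintf(
        "Nonlinear least-squares fit failed to converge (initial guess C = %.6g, k = %.4f): %s",
        start$C, start$k, conditionMessage(e)))
    }
  )

  est <- coef(fit)
  fitted_res <- est[["C"]] * mz^est[["k"]]
  ss_res <- sum((res - fitted_res)^2)
  ss_tot <- sum((res - mean(res))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_

  out <- resolution_curve(est[["C"]], est[["k"]],
                          n_points = length(mz), r_squared = r2)
  out$data <- tibble(mz = mz, resolution = res)
  out$std_errors <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                             error = function(e) NULL)
  out
}

#' Predict resolving power at an m/z value
#'
#' @param curve A `resolution_curve`.
#' @param mz m/z value(s), strictly positive.
#' @return Predicted resolving power \eqn{C \cdot mz^k} (vectorized over `mz`).
#' @export
predict_resolution <- function(curve, mz) {
  stopifnot(inherits(curve, "resolution_curve"))
  check_number(mz, "mz", allow_vector = TRUE)
  curve$coefficient * mz^curve$index
}

#' Resolution-adaptive bin width
#'
#' The full bucket width at an m/z value implied by the resolution curve:
#' \eqn{w(m/z) = m/z \,/\, R(m/z)}, i.e. the FWHM-scale width the analyzer can
#' actually resolve there. For any exponent \eqn{k < 1} the width increases
#' monotonically with m/z.
#'
#' @inheritParams predict_resolution
#' @return Bin width in Da (vectorized over `mz`).
#' @export
#' @examples
#' adaptive_bin_width(orbitrap_curve(70000), 200) # 200 / 70000 ~ 2.86e-3 Da
adaptive_bin_width <- function(curve, mz) {
  mz / predict_resolution(curve, mz)
}

#' Estimate resolution points from a profile-mode spectrum
#'
#' Detects local-maximum peaks above an intensity threshold and measures each
#' peak's full width at half maximum by linear interpolation of the two
#' half-height crossings; the resolving power of the peak is then
#' `apex_mz / FWHM`. Peaks whose half-height crossings are not bracketed
#' within the sampled profile are skipped.
#'
#' @param profile Data frame with columns `mz` and `intensity`, sorted by mz
#'   (a single profile-mode spectrum).
#' @param min_peak_frac Detection threshold as a fraction of the base-peak
#'   intensity (default 0.01).
#' @return Tibble with columns `mz`, `resolution`, `fwhm`, `height`, one row
#'   per measurable peak, in ascending mz order. Empty for spectra with no
#'   qualifying peaks.
#' @export
estimate_resolution_points <- function(profile, min_peak_frac = 0.01) {
  check_columns(profile, c("mz", "intensity"), "profile")
  check_number(min_peak_frac, "min_peak_frac")
  empty <- tibble(mz = numeric(), resolution = numeric(),
                  fwhm = numeric(), height = numeric())
  n <- nrow(profile)
  if (n < 3L) return(empty)
  mz <- as.numeric(profile$mz)
  y <- as.numeric(profile$intensity)
  if (is.unsorted(mz)) stop_validation("`profile` must be sorted by mz.")

  thr <- min_peak_frac * max(y)
  i <- 2:(n - 1)
  apex <- i[y[i] > y[i - 1] & y[i] >= y[i + 1] & y[i] >= thr]
  if (!length(apex)) return(empty)

  measure <- function(a) {
    half <- y[a] / 2
    # walk left for the half-height crossing
    l <- a
    while (l > 1 && y[l] > half) l <- l - 1
    if (y[l] > half) return(NULL)        # not bracketed on the left
    xl <- mz[l] + (mz[l + 1] - mz[l]) * (half - y[l]) / (y[l + 1] - y[l])
    # walk right
    r <- a
    while (r < n && y[r] > half) r <- r + 1
    if (y[r] > half) return(NULL)
    xr <- mz[r - 1] + (mz[r] - mz[r - 1]) * (half - y[r - 1]) / (y[r] - y[r - 1])
    fw <- xr - xl
    if (!is.finite(fw) || fw <= 0) return(NULL)
    c(mz = mz[a], resolution = mz[a] / fw, fwhm = fw, height = y[a])
  }

  rows <- Filter(Negate(is.null), lapply(apex, measure))
  if (!length(rows)) return(empty)
  out <- as_tibble(as.data.frame(do.call(rbind, rows)))
  out[order(out$mz), ]
}

#' @export
print.resolution_curve <- function(x, ...) {
  cat("<resolution_curve>\n")
  cat(sprintf("  R(m/z) = %.6g * (m/z)^%.4f\n", x$coefficient, x$index))
  cat(sprintf("  R(200) = %.0f\n", predict_resolution(x, 200)))
  if (x$n_points > 0) {
    cat(sprintf("  fitted on %d points, R^2 = %.4f\n", x$n_points, x$r_squared))
  }
  invisible(x)
}

#' @export
tidy.resolution_curve <- function(x, ...) {
  se <- x$std_errors
  tibble(
    term = c("coefficient", "index"),
    estimate = c(x$coefficient, x$index),
    std.error = if (!is.null(se)) unname(se[c("C", "k")]) else c(NA_real_, NA_real_)
  )
}

#' @export
glance.resolution_curve <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = x$n_points,
         coefficient = x$coefficient, index = x$index)
}

#' Plot a fitted resolution curve
#'
#' Scatter of the fitted (m/z, resolving power) points overlaid with the
#' power-law prediction.
#'
#' @param object A `resolution_curve`.
#' @param mz_range m/z range for the prediction line; defaults to the fitted
#'   data range, or 100--1500 for an unfitted curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.resolution_curve <- function(object, mz_range = NULL, ...) {
  if (is.null(mz_range)) {
    mz_range <- if (!is.null(object$data)) range(object$data$mz) else c(100, 1500)
  }
  grid <- tibble(mz = seq(mz_range[1], mz_range[2], length.out = 400))
  grid$resolution <- predict_resolution(object, grid$mz)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$mz, y = .data$resolution)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::labs(
      x = "m/z", y = "resolving power (m/Δm, FWHM)",
      title = sprintf("R(m/z) = %.4g · (m/z)^%.3f", object$coefficient, object$index),
      subtitle = if (object$n_points > 0)
        sprintf("fitted on %d points, R² = %.4f", object$n_points, object$r_squared)
      else NULL
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$data)) {
    p <- p + ggplot2::geom_point(data = object$data, alpha = 0.5, size = 1)
  }
  p
}
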