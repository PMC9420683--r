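#' Sampled time-enhancement curve
#'
#' A ROI time-enhancement curve: attenuation (median HU of the ROI) sampled
#' at strictly increasing times during bolus transit. The pre-contrast
#' baseline level may be attached once estimated.
#'
#' @param times Sample times in seconds, strictly increasing.
#' @param values ROI median HU per frame (absolute HU, not
#'   baseline-subtracted).
#' @param baseline_hu Optional pre-contrast HU level.
#' @return An object of class `te_curve`.
#' @export
te_curve <- function(times, values, baseline_hu = NULL) {
  stopifnot(is.numeric(times), is.numeric(values))
  if (length(times) != length(values))
    stop("`times` and `values` must have equal length")
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("times and values must all be finite")
  if (length(times) >= 2L && any(diff(times) <= 0))
    stop("`times` must be strictly increasing")
  if (!is.null(baseline_hu)) stopifnot(is.numeric(baseline_hu), length(baseline_hu) == 1L)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 baseline_hu = baseline_hu),
            class = "te_curve")
}

#' @export
print.te_curve <- function(x, ...) {
  cat(sprintf("Time-enhancement curve: %d frames, %.3g-%.3g s, HU range [%.4g, %.4g]\n",
              length(x$times), min(x$times), max(x$times),
              min(x$values), max(x$values)))
  if (!is.null(x$baseline_hu))
    cat(sprintf("  baseline %.4g HU\n", x$baseline_hu))
  invisible(x)
}

#' @export
as.data.frame.te_curve <- function(x, ...) {
  data.frame(time_s = x$times, hu = x$values)
}

#' Estimate the pre-contrast baseline of a curve
#'
#' Mean HU of the frames acquired before contrast arrival. With
#' `n_pre = NULL` (auto) the pre-arrival run is found by growing the
#' initial run of frames while each next frame stays within 2 sample
#' standard deviations of the first frame (run sd; minimum run length 2);
#' the jump at contrast arrival terminates the run.
#'
#' @param curve A [te_curve()].
#' @param n_pre Number of initial pre-contrast frames to average, or `NULL`
#'   for automatic arrival detection.
#' @return Baseline HU (scalar).
#' @export
estimate_baseline <- function(curve, n_pre = NULL) {
  stopifnot(inherits(curve, "te_curve"))
  v <- curve$values
  n <- length(v)
  if (n < 2L) stop("need at least 2 frames to estimate a baseline")
  if (!is.null(n_pre)) {
    stopifnot(is.numeric(n_pre), length(n_pre) == 1L, n_pre >= 2L, n_pre <= n)
    return(mean(v[seq_len(n_pre)]))
  }
  # absolute floor so a noiseless constant run rejects the arrival jump
  eps <- 1e-9 * max(1, abs(v[1L]))
  run <- 2L
  while (run < n) {
    s <- max(stats::sd(v[seq_len(run)]), eps)
    if (abs(v[run + 1L] - v[1L]) > 2 * s) break
    run <- run + 1L
  }
  mean(v[seq_len(run)])
}

#' Fit a gamma-variate model to a sampled time-enhancement curve
#'
#' Nonlinear least squares (Levenberg--Marquardt) of the baseline-subtracted
#' HU values against the Madsen gamma-variate [gv_enhancement()]. Starting
#' values are `y_max` = maximum observed enhancement, `t_max` = time of the
#' earliest maximal frame, `alpha` = 5; box constraints `y_max` in
#' `(0, 3 * max]`, `t_max` in `(first time, last time]`, `alpha` in
#' `[1.5, 30]` (bracketing the clinical bolus-shape range 3--15 with
#' margin).
#'
#' @param curve A [te_curve()] with at least 4 frames spanning the upslope
#'   and peak.
#' @param baseline Pre-contrast HU level; estimated with
#'   [estimate_baseline()] when `NULL`.
#' @return An object of class `gv_fit`: fields `params` ([gv_params()]),
#'   `baseline_hu`, `rmse` (HU), and `converged` (`FALSE` when the
#'   optimiser failed or `alpha` is pinned at a search bound).
#' @export
fit_gamma_variate <- function(curve, baseline = NULL) {
  stopifnot(inherits(curve, "te_curve"))
  if (length(curve$times) < 4L)
    stop("need at least 4 frames to fit a gamma-variate curve")
  if (is.null(baseline)) baseline <- estimate_baseline(curve)
  tt <- curve$times
  enh <- curve$values - baseline
  if (max(enh) <= 0)
    stop("no enhancement above baseline; cannot fit a bolus curve")

  i_peak <- which.max(enh)            # earliest maximal frame
  start <- list(y_max = max(enh),
                t_max = max(tt[i_peak], tt[1L] + 1e-6),
                alpha = 5)
  lower <- c(y_max = 1e-9, t_max = tt[1L] + 1e-9, alpha = 1.5)
  upper <- c(y_max = 3 * max(enh), t_max = tt[length(tt)], alpha = 30)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      enh ~ y_max * (tt / t_max)^alpha * exp(alpha * (1 - tt / t_max)),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12)),
    error = function(e) NULL)

  if (is.null(fit)) {
    return(structure(list(params = NULL, baseline_hu = baseline,
                          rmse = NA_real_, converged = FALSE),
                     class = "gv_fit"))
  }
  cf <- stats::coef(fit)
  pinned_alpha <- cf[["alpha"]] <= lower[["alpha"]] + 1e-6 ||
    cf[["alpha"]] >= upper[["alpha"]] - 1e-6
  params <- gv_params(y_max = cf[["y_max"]], t_max = cf[["t_max"]],
                      alpha = cf[["alpha"]])
  structure(list(params = params,
                 baseline_hu = baseline,
                 rmse = sqrt(mean(stats::residuals(fit)^2)),
                 converged = fit$convInfo$isConv && !pinned_alpha),
            class = "gv_fit")
}

#' @export
print.gv_fit <- function(x, ...) {
  if (is.null(x$params)) {
    cat("Gamma-variate fit: NOT converged\n")
  } else {
    cat(sprintf("Gamma-variate fit%s: y_max = %.4g dHU, t_max = %.4g s, alpha = %.4g\n",
                if (x$converged) "" else " (NOT converged)",
                x$params$y_max, x$params$t_max, x$params$alpha))
    cat(sprintf("  baseline %.4g HU, rmse %.4g HU\n", x$baseline_hu, x$rmse))
  }
  invisible(x)
}

#' Maximum upslope of a curve via a smoothing spline
#'
#' Fits a cubic smoothing spline (penalty selected by generalised
#' cross-validation unless `spar` is given) to the baseline-subtracted
#' values and returns the maximum of its first derivative, evaluated on a
#' grid 10 times finer than the sampling interval and restricted to times
#' at or before the observed (smoothed) peak. Smoothing removes image noise
#' but attenuates the steepest part of the curve, so on noisy data this
#' estimate tends to sit slightly below the analytic maximum slope.
#'
#' @param curve A [te_curve()] with at least 4 frames.
#' @param baseline Pre-contrast HU level; estimated with
#'   [estimate_baseline()] when `NULL`.
#' @param spar Optional smoothing parameter passed to
#'   [stats::smooth.spline()]; `NULL` uses generalised cross-validation.
#' @return A list with `max_slope` (HU/s) and `at_time` (s). A curve with
#'   no rising segment yields `max_slope = 0` with a warning.
#' @export
fit_spline_max_slope <- function(curve, baseline = NULL, spar = NULL) {
  stopifnot(inherits(curve, "te_curve"))
  if (length(curve$times) < 4L)
    stop("need at least 4 frames to fit a smoothing spline")
  if (is.null(baseline)) baseline <- estimate_baseline(curve)
  tt <- curve$times
  enh <- curve$values - baseline

  # all.knots: the default knot subset can oscillate near the flat
  # pre-arrival segment when GCV selects a near-interpolating fit
  fit <- if (is.null(spar)) stats::smooth.spline(tt, enh, all.knots = TRUE)
         else stats::smooth.spline(tt, enh, spar = spar, all.knots = TRUE)

  step <- min(diff(tt)) / 10
  grid <- seq(tt[1L], tt[length(tt)], by = step)
  smoothed <- stats::predict(fit, grid)$y
  t_peak <- grid[which.max(smoothed)]
  up <- grid <= t_peak
  deriv <- stats::predict(fit, grid[up], deriv = 1)$y
  i <- which.max(deriv)
  if (deriv[i] <= 0) {
    warning("curve has no rising segment; maximum slope reported as 0")
    return(list(max_slope = 0, at_time = grid[up][i]))
  }
  list(max_slope = deriv[i], at_time = grid[up][i])
}

#' Arterial input: fitted feeding-vessel curve summary
#'
#' The feeding-vessel (aortic) information the maximum-slope method needs:
#' the peak enhancement and the bolus-shape parameter `alpha`. Construct
#' directly when both are known (e.g. from a bolus test), or fit from a
#' sampled aortic curve with [fit_aortic_input()].
#'
#' @param peak_enhancement Peak aortic enhancement above baseline
#'   (delta-HU), `> 0`.
#' @param alpha Bolus-shape parameter.
#' @param t_max Optional time of the aortic peak (s); not needed for
#'   tissue perfusion computation.
#' @return An object of class `aortic_input`.
#' @export
aortic_input <- function(peak_enhancement, alpha, t_max = NA_real_) {
  stopifnot(is.numeric(peak_enhancement), length(peak_enhancement) == 1L,
            is.numeric(alpha), length(alpha) == 1L)
  if (!is.finite(peak_enhancement) || peak_enhancement <= 0)
    stop("`peak_enhancement` must be > 0, got ", peak_enhancement)
  if (!is.finite(alpha) || alpha <= 1)
    stop("`alpha` must be > 1, got ", alpha)
  params <- if (is.finite(t_max)) gv_params(peak_enhancement, t_max, alpha) else NULL
  structure(list(peak_enhancement = peak_enhancement, alpha = alpha,
                 t_max = t_max, params = params, fit = NULL),
            class = "aortic_input")
}

#' @export
print.aortic_input <- function(x, ...) {
  cat(sprintf("Aortic input: peak %.4g dHU, alpha %.4g%s\n",
              x$peak_enhancement, x$alpha,
              if (is.finite(x$t_max)) sprintf(", t_max %.4g s", x$t_max) else ""))
  invisible(x)
}

#' Fit the arterial input function from a sampled aortic curve
#'
#' Wraps [fit_gamma_variate()] on the aortic ROI curve and extracts the
#' study bolus parameters: peak aortic enhancement (`y_max`) and bolus
#' shape (`alpha`). A fitted `alpha` below 3 (slower than any typical
#' first-pass aortic bolus) triggers a warning, as it usually indicates a
#' tissue-like curve or a failed arrival.
#'
#' @param curve A [te_curve()] of the aortic ROI with a visible first-pass
#'   peak.
#' @param baseline Optional pre-contrast HU level.
#' @return An [aortic_input()] with the full `gv_fit` attached as `$fit`.
#' @export
fit_aortic_input <- function(curve, baseline = NULL) {
  fit <- fit_gamma_variate(curve, baseline = baseline)
  if (is.null(fit$params))
    stop("aortic gamma-variate fit failed to converge")
  if (fit$params$alpha < 3)
    warning(sprintf("fitted aortic alpha = %.3g is below the clinical bolus range (3-15); curve may not be a first-pass arterial bolus",
                    fit$params$alpha))
  out <- aortic_input(peak_enhancement = fit$params$y_max,
                      alpha = fit$params$alpha,
                      t_max = fit$params$t_max)
  out$fit <- fit
  out
}
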