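#' Perfusion from the full sampled curve (spline maximum slope)
#'
#' Classical maximum-slope perfusion: the maximal upslope of the tissue
#' time-enhancement curve, obtained from all data points smoothed with a
#' spline ([fit_spline_max_slope()]), divided by the peak feeding-vessel
#' enhancement.
#'
#' @param tissue A [te_curve()] for the tissue ROI.
#' @param aorta An [aortic_input()].
#' @param baseline Optional tissue pre-contrast HU; auto-estimated when
#'   `NULL`.
#' @return A `perfusion_estimate` with method tag `"spline_full_curve"`.
#' @export
perfusion_full_curve <- function(tissue, aorta, baseline = NULL) {
  stopifnot(inherits(tissue, "te_curve"), inherits(aorta, "aortic_input"))
  sl <- fit_spline_max_slope(tissue, baseline = baseline)
  perfusion_estimate(perfusion = sl$max_slope / aorta$peak_enhancement,
                     max_slope = sl$max_slope,
                     aortic_peak = aorta$peak_enhancement,
                     method = "spline_full_curve")
}

#' Perfusion from two scan phases
#'
#' Two-phase maximum-slope perfusion: only a baseline scan and a
#' peak-enhancement scan of the tissue are needed, together with the
#' feeding-vessel peak enhancement and bolus shape. The peak tissue
#' enhancement is `peak_hu - baseline_hu`; the unobserved maximal upslope
#' is reconstructed analytically from the gamma-variate model as
#' `y_max * k(alpha) / t_peak` with `alpha` taken from the aortic input.
#'
#' @param baseline_hu Tissue HU on the pre-contrast scan.
#' @param peak_hu Tissue HU on the peak-enhancement scan, `>= baseline_hu`.
#' @param t_peak Time of the tissue enhancement peak (s), `> 0`.
#' @param aorta An [aortic_input()] supplying peak enhancement and `alpha`.
#' @param k_mode `"linear"` (default) or `"exact"` maximum-slope factor.
#' @return A `perfusion_estimate` with method tag `"gamma_two_phase"`.
#' @examples
#' ao <- aortic_input(peak_enhancement = 350, alpha = 9)
#' est <- perfusion_two_phase(40, 140, t_peak = 35, aorta = ao)
#' perfusion_per_min(est) # about 1.14 mL/min/mL
#' @export
perfusion_two_phase <- function(baseline_hu, peak_hu, t_peak, aorta,
                                k_mode = c("linear", "exact")) {
  stopifnot(is.numeric(baseline_hu), is.numeric(peak_hu), is.numeric(t_peak),
            inherits(aorta, "aortic_input"))
  if (peak_hu < baseline_hu)
    stop("`peak_hu` must be >= `baseline_hu` (no negative enhancement)")
  if (!is.finite(t_peak) || t_peak <= 0)
    stop("`t_peak` must be > 0, got ", t_peak)
  params <- gv_params(y_max = peak_hu - baseline_hu, t_max = t_peak,
                      alpha = aorta$alpha)
  perfusion_from_params(params, aorta$peak_enhancement, k_mode = k_mode)
}

#' Compare two perfusion measurement methods
#'
#' Linear regression of method 2 on method 1 (ordinary least squares) plus
#' Bland--Altman agreement statistics of the paired differences
#' `y - x`: bias (mean difference) and 95% limits of agreement
#' `bias +/- 1.96 * sd` (sample standard deviation, `n - 1` denominator).
#' `r2` is the squared Pearson correlation, identical to the OLS R-squared
#' with intercept.
#'
#' @param x,y Equal-length numeric vectors of paired estimates (method 1
#'   and method 2), `n >= 3`.
#' @return An object of class `method_comparison`: `slope`, `intercept`,
#'   `r2`, `p_value` (t-test on the slope), `bias`, `loa_lower`,
#'   `loa_upper`, `n`, and `difference` (`"y - x"`).
#' @export
compare_methods <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired values")
  if (stats::var(x) == 0)
    stop("`x` has zero variance; regression of y on x is undefined")

  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  r <- stats::cor(x, y)
  # suppressed: summary.lm warns on an exactly collinear (perfect) fit
  p <- suppressWarnings(summary(fit)$coefficients["x", "Pr(>|t|)"])

  d <- y - x
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(slope = unname(cf[2L]), intercept = unname(cf[1L]),
                 r2 = r^2, p_value = unname(p),
                 bias = bias,
                 loa_lower = bias - 1.96 * s,
                 loa_upper = bias + 1.96 * s,
                 n = length(x), difference = "y - x"),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Method comparison (n = %d):\n", x$n))
  cat(sprintf("  regression: y = %.4g + %.4g x,  r2 = %.3f, p = %.3g\n",
              x$intercept, x$slope, x$r2, x$p_value))
  cat(sprintf("  Bland-Altman (%s): bias %.4g, LoA [%.4g, %.4g]\n",
              x$difference, x$bias, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Image-quality metrics of a dynamic study
#'
#' Signal-to-noise ratio of the aortic ROI (mean pre-contrast aortic HU
#' divided by the ROI standard deviation) and contrast-to-noise ratio
#' against a paravertebral muscle ROI,
#' `CNR = (aortic mean HU - muscle mean HU) / muscle HU standard deviation`.
#'
#' @param aortic_precontrast_mean Mean pre-contrast aortic HU.
#' @param aortic_roi_sd Aortic ROI HU standard deviation, `> 0`.
#' @param muscle_mean Mean muscle HU.
#' @param muscle_sd Muscle ROI HU standard deviation, `> 0`.
#' @return A list with `snr` and `cnr`.
#' @export
snr_cnr <- function(aortic_precontrast_mean, aortic_roi_sd,
                    muscle_mean, muscle_sd) {
  stopifnot(is.numeric(aortic_precontrast_mean), is.numeric(aortic_roi_sd),
            is.numeric(muscle_mean), is.numeric(muscle_sd))
  if (aortic_roi_sd <= 0 || muscle_sd <= 0)
    stop("ROI standard deviations must be > 0")
  list(snr = aortic_precontrast_mean / aortic_roi_sd,
       cnr = (aortic_precontrast_mean - muscle_mean) / muscle_sd)
}

#' Pairwise perfusion and enhancement ratios across organs
#'
#' For every unordered pair of organs, computes the ratio of their
#' perfusion estimates and the ratio of their peak enhancements. When the
#' organs share the same feeding vessel and bolus kinetics the two columns
#' coincide (relative perfusion equals relative enhancement), which is
#' the basis for feeding-vessel-free relative perfusion.
#'
#' @param perfusions Named numeric vector (1/s or any common unit) or
#'   named list of `perfusion_estimate` objects, one per organ.
#' @param enhancements Named numeric vector of peak enhancements
#'   (delta-HU) with the same organ names.
#' @return A data frame with columns `organ_1`, `organ_2`,
#'   `perfusion_ratio`, `enhancement_ratio`. Pairs with a zero denominator
#'   are skipped with a warning.
#' @export
ratio_table <- function(perfusions, enhancements) {
  if (is.list(perfusions))
    perfusions <- vapply(perfusions, function(p) {
      if (inherits(p, "perfusion_estimate")) p$perfusion else as.numeric(p)
    }, numeric(1))
  stopifnot(is.numeric(perfusions), is.numeric(enhancements))
  organs <- names(perfusions)
  if (is.null(organs) || is.null(names(enhancements)))
    stop("`perfusions` and `enhancements` must be named by organ")
  if (!setequal(organs, names(enhancements)))
    stop("organ names of `perfusions` and `enhancements` differ")
  if (length(organs) < 2L) stop("need at least 2 organs")
  enhancements <- enhancements[organs]

  pairs <- utils::combn(organs, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    o1 <- pairs[1L, j]; o2 <- pairs[2L, j]
    if (perfusions[[o2]] == 0 || enhancements[[o2]] == 0) {
      warning(sprintf("skipping pair %s/%s: zero denominator", o1, o2))
      return(NULL)
    }
    data.frame(organ_1 = o1, organ_2 = o2,
               perfusion_ratio = perfusions[[o1]] / perfusions[[o2]],
               enhancement_ratio = enhancements[[o1]] / enhancements[[o2]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
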