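#' Gamma-variate curve parameters (Madsen form)
#'
#' Bundle of the three parameters that define a single bolus
#' time-enhancement curve in the Madsen parameterisation
#' \deqn{y(t) = y_{max} \, \tau^{\alpha} e^{\alpha (1 - \tau)}, \qquad
#'       \tau = t / t_{max},}
#' where \code{y_max} is the peak enhancement above baseline (in Hounsfield
#' units, HU), \code{t_max} the time of the peak in seconds, and
#' \code{alpha} the dimensionless bolus-shape parameter (steeper bolus for
#' larger \code{alpha}; clinical aortic boluses fall in roughly 3--15).
#'
#' @param y_max Peak enhancement above baseline (delta-HU), `>= 0`.
#' @param t_max Time of the enhancement peak in seconds, `> 0`.
#' @param alpha Dimensionless bolus-shape parameter, `> 1`.
#'
#' @return An object of class `gv_params`.
#' @examples
#' p <- gv_params(y_max = 100, t_max = 35, alpha = 9)
#' gv_enhancement(p, c(0, 17.5, 35))
#' @export
gv_params <- function(y_max, t_max, alpha) {
  stopifnot(is.numeric(y_max), length(y_max) == 1L,
            is.numeric(t_max), length(t_max) == 1L,
            is.numeric(alpha), length(alpha) == 1L)
  if (!is.finite(y_max) || y_max < 0)
    stop("`y_max` must be finite and >= 0, got ", y_max)
  if (!is.finite(t_max) || t_max <= 0)
    stop("`t_max` must be finite and > 0, got ", t_max)
  if (!is.finite(alpha) || alpha <= 1)
    stop("`alpha` must be finite and > 1 (gamma-variate shape), got ", alpha)
  structure(list(y_max = y_max, t_max = t_max, alpha = alpha),
            class = "gv_params")
}

#' @export
print.gv_params <- function(x, ...) {
  cat(sprintf("Gamma-variate curve: y_max = %.4g dHU, t_max = %.4g s, alpha = %.4g\n",
              x$y_max, x$t_max, x$alpha))
  invisible(x)
}

#' Contrast injection protocol
#'
#' Parameters needed to predict the peak aortic enhancement from first
#' principles: the injected contrast is assumed to be diluted into the whole
#' cardiac output before entering the arterial tree, so the blood iodine
#' concentration at peak is `flow_rate * iodine_concentration /
#' cardiac_output`, converted to enhancement by a kVp-dependent HU constant.
#'
#' @param flow_rate Contrast injection rate (mL/s).
#' @param iodine_concentration Contrast agent concentration (mgI/mL).
#' @param cardiac_output Cardiac output (mL/s); 5 L/min is about 83 mL/s.
#' @param hu_constant Enhancement per unit blood iodine concentration
#'   (HU per mgI/mL). The default 26.18 applies at 120 kVp; at other tube
#'   voltages the constant must be supplied by the user.
#'
#' @return An object of class `injection_protocol`.
#' @seealso [predict_aortic_peak()]
#' @export
injection_protocol <- function(flow_rate, iodine_concentration, cardiac_output,
                               hu_constant = 26.18) {
  stopifnot(is.numeric(flow_rate), is.numeric(iodine_concentration),
            is.numeric(cardiac_output), is.numeric(hu_constant))
  if (flow_rate < 0 || iodine_concentration < 0 || hu_constant < 0)
    stop("injection protocol fields must be >= 0")
  if (!is.finite(cardiac_output) || cardiac_output <= 0)
    stop("`cardiac_output` must be > 0, got ", cardiac_output)
  structure(list(flow_rate = flow_rate,
                 iodine_concentration = iodine_concentration,
                 cardiac_output = cardiac_output,
                 hu_constant = hu_constant),
            class = "injection_protocol")
}

check_times <- function(times) {
  if (!is.numeric(times) || any(!is.finite(times)))
    stop("`times` must be finite numeric values (seconds)")
  if (any(times < 0))
    stop("`times` must be >= 0; got negative time ",
         min(times[times < 0]))
  invisible(times)
}

#' Evaluate a gamma-variate enhancement curve
#'
#' Computes the Madsen gamma-variate enhancement
#' `y_max * tau^alpha * exp(alpha * (1 - tau))` with `tau = times / t_max`,
#' i.e. the enhancement above baseline at each requested time. The curve is
#' 0 at time 0, rises to exactly `y_max` at `t_max`, and decays towards 0
#' afterwards (unimodal on `[0, Inf)`).
#'
#' @param params A [gv_params()] object.
#' @param times Numeric vector of times in seconds, `>= 0`.
#' @return Numeric vector of enhancements (delta-HU).
#' @export
gv_enhancement <- function(params, times) {
  stopifnot(inherits(params, "gv_params"))
  check_times(times)
  tau <- times / params$t_max
  params$y_max * tau^params$alpha * exp(params$alpha * (1 - tau))
}

#' Slope of a gamma-variate enhancement curve
#'
#' First derivative of the Madsen curve with respect to physical time
#' (HU/s). The Madsen derivative is taken with respect to the dimensionless
#' time `tau = t / t_max`, so the physical slope carries an extra `1/t_max`
#' chain factor:
#' \deqn{y'(t) = \frac{y_{max}\,\alpha}{t_{max}}
#'   \left(\tau^{\alpha-1} - \tau^{\alpha}\right) e^{\alpha(1-\tau)}.}
#' The slope is positive on the upslope, exactly 0 at `t_max`, and negative
#' during washout.
#'
#' @inheritParams gv_enhancement
#' @return Numeric vector of slopes (HU/s).
#' @export
gv_slope <- function(params, times) {
  stopifnot(inherits(params, "gv_params"))
  check_times(times)
  tau <- times / params$t_max
  a <- params$alpha
  params$y_max * a * (tau^(a - 1) - tau^a) * exp(a * (1 - tau)) / params$t_max
}

#' Inflection points of the gamma-variate curve
#'
#' The second derivative of the Madsen curve vanishes at the dimensionless
#' times `tau = (alpha +/- sqrt(alpha)) / alpha`. The minus root lies on the
#' upslope (in `(0, 1)`) and is where the slope is maximal; the plus root is
#' the washout inflection.
#'
#' @param alpha Bolus-shape parameter, `> 1`.
#' @return Named numeric vector `c(ascending = , descending = )` of
#'   dimensionless times (multiply by `t_max` for seconds).
#' @examples
#' gv_inflection_times(9) # c(2/3, 4/3)
#' @export
gv_inflection_times <- function(alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L)
  if (!is.finite(alpha) || alpha <= 1)
    stop("`alpha` must be > 1 for distinct inflection points inside the upslope, got ", alpha)
  s <- sqrt(alpha)
  c(ascending = (alpha - s) / alpha, descending = (alpha + s) / alpha)
}

#' Exact maximum-slope factor k(alpha)
#'
#' The maximum slope of a gamma-variate curve equals `y_max * k / t_max`
#' where the dimensionless factor `k` depends only on the bolus shape:
#' `k = alpha * (tau^(alpha-1) - tau^alpha) * exp(alpha*(1-tau))` evaluated
#' at the ascending inflection root `tau = (alpha - sqrt(alpha)) / alpha`.
#' `k` is positive and increases with `alpha` (steeper bolus, steeper
#' upslope relative to peak).
#'
#' @param alpha Bolus-shape parameter(s), `> 1`; vectorised.
#' @return Numeric vector of `k` values.
#' @seealso [k_linear()] for the linearised approximation used by the
#'   two-phase perfusion equations.
#' @export
k_exact <- function(alpha) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) || any(alpha <= 1))
    stop("`alpha` must be finite and > 1")
  tau <- (alpha - sqrt(alpha)) / alpha
  alpha * (tau^(alpha - 1) - tau^alpha) * exp(alpha * (1 - tau))
}

#' Linearised maximum-slope factor k(alpha)
#'
#' Over the clinical range of bolus shapes (`alpha` in 3--15) the exact
#' factor [k_exact()] is nearly linear in `alpha`; the fitted line is
#' `k = 1.502 + 0.092016 * alpha` (within 2% of the exact value on that
#' range). This linearised form is the default used by the two-phase
#' perfusion equations.
#'
#' @param alpha Bolus-shape parameter(s); vectorised. Values outside
#'   `[3, 15]` trigger a warning (the line was fitted on that range).
#' @return Numeric vector `1.502 + 0.092016 * alpha`.
#' @export
k_linear <- function(alpha) {
  stopifnot(is.numeric(alpha))
  out_of_range <- is.finite(alpha) & (alpha < 3 | alpha > 15)
  if (any(out_of_range))
    warning("k_linear() was calibrated on alpha in [3, 15]; got alpha = ",
            paste(signif(alpha[out_of_range], 4), collapse = ", "))
  1.502 + 0.092016 * alpha
}

k_factor <- function(alpha, k_mode = c("linear", "exact")) {
  k_mode <- match.arg(k_mode)
  switch(k_mode, linear = k_linear(alpha), exact = k_exact(alpha))
}

#' Analytic maximum slope of a gamma-variate curve
#'
#' Maximum upslope `y_max * k(alpha) / t_max` in HU/s, using either the
#' exact factor [k_exact()] or its linearisation [k_linear()] (the default,
#' as in the closed-form two-phase perfusion equations).
#'
#' @param params A [gv_params()] object.
#' @param k_mode `"linear"` (default) or `"exact"`.
#' @return Maximum slope in HU/s.
#' @export
gv_max_slope <- function(params, k_mode = c("linear", "exact")) {
  stopifnot(inherits(params, "gv_params"))
  params$y_max * k_factor(params$alpha, k_mode) / params$t_max
}

#' Perfusion from gamma-variate curve parameters
#'
#' Maximum slope method: perfusion is the maximal upslope of the tissue
#' time-enhancement curve divided by the peak enhancement of the feeding
#' vessel,
#' \deqn{P = \frac{y_{max} \, k(\alpha) / t_{max}}{\text{peak feeding
#'   vessel enhancement}}.}
#' Perfusion is returned in 1/s (mL/s per mL of tissue); use
#' [perfusion_per_min()] for the conventional mL/min/mL presentation.
#'
#' @param params Tissue curve parameters ([gv_params()]); `alpha` is the
#'   bolus shape, normally taken from the aortic curve.
#' @param aortic_peak Peak feeding-vessel enhancement (delta-HU), `> 0`.
#' @inheritParams gv_max_slope
#' @return A `perfusion_estimate` with method tag `"gamma_two_phase"`.
#' @export
perfusion_from_params <- function(params, aortic_peak,
                                  k_mode = c("linear", "exact")) {
  stopifnot(inherits(params, "gv_params"))
  if (!is.numeric(aortic_peak) || length(aortic_peak) != 1L ||
      !is.finite(aortic_peak) || aortic_peak <= 0)
    stop("`aortic_peak` must be a single finite value > 0, got ", aortic_peak)
  ms <- gv_max_slope(params, k_mode)
  perfusion_estimate(perfusion = ms / aortic_peak, max_slope = ms,
                     aortic_peak = aortic_peak, method = "gamma_two_phase")
}

#' Predicted peak tissue enhancement for a given perfusion
#'
#' Inverts the maximum-slope perfusion equation: the peak tissue
#' enhancement is
#' \deqn{y_{max} = \frac{P \times \text{peak feeding vessel enhancement}}
#'   {k(\alpha) / t_{max}},}
#' i.e. arterial-phase enhancement is a linear, origin-crossing function of
#' perfusion once the aortic peak and bolus shape are fixed. Exact inverse
#' of [perfusion_from_params()] for matching `k_mode`.
#'
#' @param perfusion Perfusion in 1/s (mL/s per mL tissue), `>= 0`. Divide a
#'   mL/min/mL value by 60.
#' @param aortic_peak Peak feeding-vessel enhancement (delta-HU), `> 0`.
#' @param t_max Time of the tissue enhancement peak (s).
#' @param alpha Bolus-shape parameter.
#' @inheritParams gv_max_slope
#' @return Predicted peak tissue enhancement (delta-HU).
#' @examples
#' # pancreas at 1.15 mL/min/mL with a 350 dHU aortic peak: about 100 dHU
#' enhancement_from_perfusion(1.15 / 60, 350, t_max = 35, alpha = 9)
#' @export
enhancement_from_perfusion <- function(perfusion, aortic_peak, t_max, alpha,
                                       k_mode = c("linear", "exact")) {
  stopifnot(is.numeric(perfusion), is.numeric(aortic_peak))
  if (any(perfusion < 0)) stop("`perfusion` must be >= 0")
  if (any(!is.finite(aortic_peak)) || any(aortic_peak <= 0))
    stop("`aortic_peak` must be > 0")
  if (any(t_max <= 0)) stop("`t_max` must be > 0")
  perfusion * aortic_peak / (k_factor(alpha, k_mode) / t_max)
}

#' Predict the peak aortic enhancement from the injection protocol
#'
#' Dilution model: all injected contrast mixes into the cardiac output, so
#' the peak blood iodine concentration is `flow_rate *
#' iodine_concentration / cardiac_output`, and the peak enhancement is that
#' concentration times the kVp-dependent HU constant.
#'
#' @param protocol An [injection_protocol()].
#' @return Predicted peak aortic enhancement (delta-HU).
#' @examples
#' # 3.2 mL/s of 350 mgI/mL contrast, cardiac output 83 mL/s, 120 kVp
#' predict_aortic_peak(injection_protocol(3.2, 350, 83)) # about 353 dHU
#' @export
predict_aortic_peak <- function(protocol) {
  stopifnot(inherits(protocol, "injection_protocol"))
  protocol$flow_rate * protocol$iodine_concentration * protocol$hu_constant /
    protocol$cardiac_output
}

#' Perfusion ratio of two ROIs from their peak enhancements
#'
#' For two regions fed by the same vessel (same aortic peak) with shared
#' bolus shape and peak time, the `k / t_max` and aortic-peak factors cancel
#' in the ratio of maximum-slope perfusions, leaving simply the ratio of
#' peak tissue enhancements: relative perfusion needs no arterial input at
#' all.
#'
#' @param y_max_1,y_max_2 Peak enhancements (delta-HU) of the two ROIs;
#'   `y_max_2 > 0`.
#' @return The dimensionless ratio `y_max_1 / y_max_2`.
#' @export
perfusion_ratio_from_enhancement <- function(y_max_1, y_max_2) {
  stopifnot(is.numeric(y_max_1), is.numeric(y_max_2))
  if (any(y_max_2 <= 0)) stop("`y_max_2` must be > 0")
  y_max_1 / y_max_2
}

#' Perfusion estimate container
#'
#' Holds a perfusion value in 1/s (mL/s per mL of tissue) together with the
#' intermediates of the maximum-slope computation and a tag for the method
#' that produced it.
#'
#' @param perfusion Perfusion in 1/s.
#' @param max_slope Maximum tissue upslope (HU/s).
#' @param aortic_peak Peak feeding-vessel enhancement (delta-HU).
#' @param method `"spline_full_curve"` or `"gamma_two_phase"`.
#' @return An object of class `perfusion_estimate`.
#' @export
perfusion_estimate <- function(perfusion, max_slope, aortic_peak,
                               method = c("gamma_two_phase", "spline_full_curve")) {
  method <- match.arg(method)
  stopifnot(is.numeric(perfusion), is.numeric(max_slope), is.numeric(aortic_peak))
  structure(list(perfusion = perfusion, max_slope = max_slope,
                 aortic_peak = aortic_peak, method = method),
            class = "perfusion_estimate")
}

#' Perfusion in mL/min/mL
#'
#' Presentation accessor: perfusion estimates are stored in 1/s; the
#' conventional clinical unit is mL/min per mL of tissue (factor 60).
#'
#' @param x A `perfusion_estimate` or a numeric perfusion in 1/s.
#' @return Perfusion in mL/min/mL.
#' @export
perfusion_per_min <- function(x) {
  if (inherits(x, "perfusion_estimate")) x <- x$perfusion
  stopifnot(is.numeric(x))
  60 * x
}

#' @export
print.perfusion_estimate <- function(x, ...) {
  cat(sprintf("Perfusion: %.4g mL/min/mL (%.4g 1/s) [%s]\n",
              perfusion_per_min(x), x$perfusion, x$method))
  cat(sprintf("  max slope %.4g HU/s, aortic peak %.4g dHU\n",
              x$max_slope, x$aortic_peak))
  invisible(x)
}
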