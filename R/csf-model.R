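#' Truncated log-parabola CSF parameters
#'
#' Container for the four-parameter contrast sensitivity function used
#' throughout the package. The CSF is a parabola in log10 sensitivity over
#' log10 spatial frequency, with the low-frequency limb flattened
#' ("truncated") at `peak_gain * 10^-truncation`.
#'
#' @param peak_gain Linear sensitivity at the peak (dimensionless, > 0).
#' @param peak_frequency Spatial frequency of the peak, cycles per degree.
#' @param bandwidth Full width at half maximum of the parabola, in
#'   log10-frequency units (> 0). One octave equals `log10(2)` of these units.
#' @param truncation Drop, in log10-sensitivity units, from the peak to the
#'   low-frequency plateau (>= 0).
#' @return An object of class `csf_params`.
#' @examples
#' p <- csf_params(peak_gain = 100, peak_frequency = 4,
#'                 bandwidth = 0.6, truncation = 0.5)
#' csf_sensitivity(4, p)    # 100 at the peak
#' @export
csf_params <- function(peak_gain, peak_frequency, bandwidth, truncation) {
  for (v in list(peak_gain, peak_frequency, bandwidth, truncation)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_domain("CSF parameters must be finite numeric scalars")
  }
  if (peak_gain <= 0) stop_domain("peak_gain must be > 0")
  if (peak_frequency <= 0) stop_domain("peak_frequency must be > 0")
  if (bandwidth <= 0) stop_domain("bandwidth must be > 0")
  if (truncation < 0) stop_domain("truncation must be >= 0")
  structure(
    list(peak_gain = peak_gain, peak_frequency = peak_frequency,
         bandwidth = bandwidth, truncation = truncation),
    class = "csf_params"
  )
}

#' @export
print.csf_params <- function(x, ...) {
  cat(sprintf(
    "CSF: peak gain %.4g, peak frequency %.3g cpd, bandwidth %.3g log10 units, truncation %.3g\n",
    x$peak_gain, x$peak_frequency, x$bandwidth, x$truncation))
  invisible(x)
}

#' Log10 contrast sensitivity of the truncated log-parabola
#'
#' The underlying parabola is
#' `log10 S0(f) = log10(peak_gain) - 4 log10(2) * ((log10 f - log10 fmax) / bandwidth)^2`.
#' Below the peak frequency, where the parabola would fall beneath
#' `log10(peak_gain) - truncation`, sensitivity is held at that plateau.
#' Above the peak the parabola applies unmodified.
#'
#' @param f Spatial frequency in cycles per degree (vectorised, all > 0).
#' @param params A [csf_params()] object.
#' @return Log10 sensitivity at each `f`.
#' @export
csf_log_sensitivity <- function(f, params) {
  stopifnot(inherits(params, "csf_params"))
  if (!is.numeric(f) || any(!is.finite(f)) || any(f <= 0))
    stop_domain("spatial frequency must be finite and > 0")
  lg <- log10(params$peak_gain)
  lf <- log10(f)
  lf0 <- log10(params$peak_frequency)
  parab <- lg - 4 * log10(2) * ((lf - lf0) / params$bandwidth)^2
  plateau <- lg - params$truncation
  ifelse(lf < lf0 & parab < plateau, plateau, parab)
}

#' Linear contrast sensitivity
#'
#' `10^csf_log_sensitivity(f, params)`.
#'
#' @inheritParams csf_log_sensitivity
#' @return Linear sensitivity (reciprocal of threshold Michelson contrast).
#' @export
csf_sensitivity <- function(f, params) {
  10^csf_log_sensitivity(f, params)
}

#' Area under the log CSF (AULCSF)
#'
#' Trapezoidal integral of `max(0, log10 S(f))` over log10 frequency. The
#' default range 1.5--18 cpd is the classic AULCSF definition; negative log
#' sensitivities (threshold contrast above 100%) are clipped to zero by
#' default so the area measures useful contrast vision only.
#'
#' @param params A [csf_params()] object, or any object with a
#'   [sensitivity_at()] method (e.g. a binocular profile).
#' @param f_lo,f_hi Integration bounds in cycles per degree, `0 < f_lo < f_hi`.
#' @param n_points Number of trapezoid nodes (>= 2).
#' @param clip_negative Clip log sensitivity at zero before integrating.
#' @return Area in log10-sensitivity x log10-frequency units.
#' @export
aulcsf <- function(params, f_lo = 1.5, f_hi = 18, n_points = 1000,
                   clip_negative = TRUE) {
  if (!is.numeric(f_lo) || !is.numeric(f_hi) || f_lo <= 0 || f_hi <= f_lo)
    stop_domain("need 0 < f_lo < f_hi")
  if (n_points < 2) stop_domain("n_points must be >= 2")
  x <- seq(log10(f_lo), log10(f_hi), length.out = n_points)
  y <- log10(sensitivity_at(params, 10^x))
  if (clip_negative) y <- pmax(0, y)
  trapz_uniform(y, x[2] - x[1])
}

#' High-frequency cut-off of the CSF (CSF acuity)
#'
#' The spatial frequency above the peak at which sensitivity falls to
#' `criterion` (default 1.0, i.e. 100% contrast). Closed form on the
#' high-frequency limb, where truncation never applies:
#' `log10 f_cut = log10 fmax + (bandwidth / 2) * sqrt(log10(peak_gain / criterion) / log10 2)`.
#'
#' @param params A [csf_params()] object.
#' @param criterion_sensitivity Criterion linear sensitivity (> 0).
#' @return Cut-off frequency in cycles per degree. If `peak_gain` is below
#'   the criterion the cut-off does not exist: `NA_real_` is returned with
#'   attribute `below_criterion = TRUE`.
#' @export
csf_acuity <- function(params, criterion_sensitivity = 1.0) {
  stopifnot(inherits(params, "csf_params"))
  if (!is.numeric(criterion_sensitivity) || criterion_sensitivity <= 0)
    stop_domain("criterion_sensitivity must be > 0")
  if (params$peak_gain < criterion_sensitivity)
    return(structure(NA_real_, below_criterion = TRUE))
  lf0 <- log10(params$peak_frequency)
  drop <- log10(params$peak_gain / criterion_sensitivity)
  10^(lf0 + (params$bandwidth / 2) * sqrt(drop / log10(2)))
}

#' Log10 threshold contrast from linear sensitivity
#'
#' Sensitivity is the reciprocal of threshold contrast, so the log10
#' threshold is `-log10(S)`. Links the CSF to the psychometric function's
#' threshold parameter.
#'
#' @param S Linear sensitivity (> 0, vectorised).
#' @return Log10 Michelson threshold contrast.
#' @export
threshold_from_sensitivity <- function(S) {
  if (any(S <= 0)) stop_domain("sensitivity must be > 0")
  -log10(S)
}

#' @rdname threshold_from_sensitivity
#' @param tau Log10 threshold contrast.
#' @export
sensitivity_from_threshold <- function(tau) 10^(-tau)

#' Psychometric function specification
#'
#' Parameters of the cumulative-Gaussian psychometric function for the
#' 10-alternative forced-choice letter task,
#' `P(c, tau) = guess + (1 - guess - lapse) * pnorm(k * (c - tau))`,
#' where `c` and `tau` are log10 Michelson contrasts and
#' `k = slope_constant * slope` by default. The slope expression is
#' configurable through `slope_fun` because published typography for the
#' slope term is ambiguous; see [calibrate_psychometric_slope()] for a
#' calibration anchored to the binocular probability-summation gain.
#'
#' @param guess_rate Guessing rate, 0.1 for 10-AFC.
#' @param lapse_rate Lapse rate. The default 0.04 makes the probability at
#'   threshold exactly `0.1 + (1 - 0.1 - 0.04) / 2 = 0.53`, the detection
#'   criterion used throughout.
#' @param slope Psychometric slope parameter (dimensionless, > 0).
#' @param slope_constant Multiplier applied to `slope` (default 0.6).
#' @param slope_fun Optional `function(slope, slope_constant)` returning the
#'   effective slope per log10-contrast unit; overrides the default product.
#' @return An object of class `psychometric_spec` with the effective slope
#'   stored in field `k`.
#' @export
psychometric_spec <- function(guess_rate = 0.1, lapse_rate = 0.04,
                              slope = 0.25, slope_constant = 0.6,
                              slope_fun = NULL) {
  if (guess_rate < 0 || guess_rate >= 1 - lapse_rate || lapse_rate < 0)
    stop_domain("need 0 <= guess_rate < 1 - lapse_rate <= 1")
  if (slope <= 0) stop_domain("slope must be > 0")
  k <- if (is.null(slope_fun)) slope_constant * slope else slope_fun(slope, slope_constant)
  if (!is.numeric(k) || k <= 0) stop_domain("effective slope must be > 0")
  structure(
    list(guess_rate = guess_rate, lapse_rate = lapse_rate, slope = slope,
         slope_constant = slope_constant, k = k),
    class = "psychometric_spec"
  )
}

#' @export
print.psychometric_spec <- function(x, ...) {
  cat(sprintf(
    "Psychometric spec: guess %.3g, lapse %.3g, effective slope %.4g per log10 contrast\n",
    x$guess_rate, x$lapse_rate, x$k))
  invisible(x)
}

#' Probability of a correct response
#'
#' Cumulative-Gaussian psychometric function in log10 contrast. At
#' `c = tau` the Gaussian term is `pnorm(0) = 1/2` regardless of slope, so
#' the probability is `guess + (1 - guess - lapse) / 2` (0.53 with the
#' defaults) -- the definition of threshold used by the analysis.
#'
#' @param c Log10 Michelson stimulus contrast (vectorised).
#' @param tau Log10 Michelson threshold contrast (vectorised).
#' @param spec A [psychometric_spec()].
#' @return Probability correct, in `[guess_rate, 1 - lapse_rate]`.
#' @export
psychometric_p <- function(c, tau, spec = psychometric_spec()) {
  stopifnot(inherits(spec, "psychometric_spec"))
  spec$guess_rate +
    (1 - spec$guess_rate - spec$lapse_rate) * stats::pnorm(spec$k * (c - tau))
}

#' Threshold probability implied by a psychometric spec
#'
#' `guess + (1 - guess - lapse) / 2`; 0.53 for the default 10-AFC spec.
#'
#' @param spec A [psychometric_spec()].
#' @export
criterion_probability <- function(spec = psychometric_spec()) {
  spec$guess_rate + (1 - spec$guess_rate - spec$lapse_rate) / 2
}

#' Calibrate the psychometric slope to a probability-summation gain
#'
#' Two eyes of identical sensitivity, combined as independent detectors
#' (guessing-corrected probability summation), reach the threshold criterion
#' at a contrast lower than the monocular threshold by a factor that depends
#' only on the psychometric slope. The binocular-vision literature puts this
#' probability-summation gain at about 1.2. This function returns the spec
#' whose effective slope produces exactly the requested gain, in closed form:
#' the per-eye corrected probability at the binocular threshold is
#' `1 - sqrt(1 - C)` with `C` the corrected criterion, and the slope is the
#' normal quantile at that probability divided by `-log10(gain)`.
#'
#' @param summation_gain Target equal-eye probability-summation sensitivity
#'   gain (> 1); default 1.2.
#' @param guess_rate,lapse_rate,slope_constant Passed to [psychometric_spec()].
#' @return A `psychometric_spec` whose `slope` is set so that
#'   `slope_constant * slope` equals the calibrated effective slope.
#' @export
calibrate_psychometric_slope <- function(summation_gain = 1.2,
                                         guess_rate = 0.1, lapse_rate = 0.04,
                                         slope_constant = 0.6) {
  if (summation_gain <= 1) stop_domain("summation_gain must be > 1")
  crit <- guess_rate + (1 - guess_rate - lapse_rate) / 2
  corrected <- (crit - guess_rate) / (1 - guess_rate)
  per_eye_corr <- 1 - sqrt(1 - corrected)
  per_eye_p <- guess_rate + (1 - guess_rate) * per_eye_corr
  z <- stats::qnorm((per_eye_p - guess_rate) / (1 - guess_rate - lapse_rate))
  k <- -z / log10(summation_gain)
  psychometric_spec(guess_rate = guess_rate, lapse_rate = lapse_rate,
                    slope = k / slope_constant, slope_constant = slope_constant)
}

#' Sensitivity lookup generic
#'
#' Linear contrast sensitivity at given frequencies, for CSF parameter sets
#' and for tabulated binocular profiles alike. Lets the adaptive engine and
#' the summation analysis consume either representation.
#'
#' @param object A `csf_params` or `binocular_profile` object.
#' @param f Spatial frequencies, cycles per degree.
#' @export
sensitivity_at <- function(object, f) UseMethod("sensitivity_at")

#' @export
sensitivity_at.csf_params <- function(object, f) csf_sensitivity(f, object)
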