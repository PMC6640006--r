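#' Binocular summation index
#'
#' Ratio of binocular to dominant-eye AULCSF. Values above 1 indicate a
#' binocular advantage.
#'
#' @param aulcsf_bin,aulcsf_de AULCSF of the binocular and dominant-eye
#'   conditions (`aulcsf_de > 0`).
#' @export
summation_index <- function(aulcsf_bin, aulcsf_de) {
  if (any(aulcsf_de <= 0)) stop_domain("aulcsf_de must be > 0")
  aulcsf_bin / aulcsf_de
}

#' Guessing correction of a detection probability
#'
#' Removes the guessing floor of the forced-choice task:
#' `(p - guess) / (1 - guess)`, clamped to `[0, 1]`.
#'
#' @param p Probability correct (vectorised, in `[0, 1]`).
#' @param guess Guessing rate (0.1 for 10-AFC; must be < 1).
#' @export
correct_for_guessing <- function(p, guess = 0.1) {
  if (guess >= 1 || guess < 0) stop_domain("guess rate must be in [0, 1)")
  if (any(p < 0 | p > 1)) stop_domain("probabilities must lie in [0, 1]")
  pmin(1, pmax(0, (p - guess) / (1 - guess)))
}

#' @rdname correct_for_guessing
#' @export
invert_guessing_correction <- function(p, guess = 0.1) {
  guess + (1 - guess) * p
}

#' Expected binocular probability under probability summation
#'
#' Independent-detector combination of the two monocular detection
#' probabilities, with guessing correction: each term is corrected
#' (`(p - guess)/(1 - guess)`), combined as `c1 + c2 - c1 c2`, and the
#' correction is inverted on the result. Symmetric in its arguments;
#' collapses to `p1 + p2 - p1 p2` when `guess = 0`; never below
#' `max(p_nde, p_de)` when both inputs are at or above the guessing floor.
#'
#' @param p_nde,p_de Monocular probabilities correct (vectorised).
#' @param guess Guessing rate.
#' @export
expected_binocular_probability <- function(p_nde, p_de, guess = 0.1) {
  c1 <- correct_for_guessing(p_nde, guess)
  c2 <- correct_for_guessing(p_de, guess)
  invert_guessing_correction(c1 + c2 - c1 * c2, guess)
}

#' Detection profile: binocular thresholds seen through monocular eyes
#'
#' The finer-grained binocular analysis. At each of `n_frequencies`
#' log-spaced spatial frequencies, the binocular threshold contrast (the
#' contrast the binocular system detects at the criterion probability,
#' i.e. `1 / S_bin(f)`) is evaluated under each monocular psychometric
#' function, giving per-frequency monocular detection probabilities. These
#' are averaged across frequency (probabilities are clamped to
#' `[guess, 1 - lapse]` first), and the expected binocular probability is
#' obtained by probability summation of the two monocular means
#' (`order = "mean_first"`, as in the published analysis) or by summing per
#' frequency and then averaging (`order = "frequency_first"`).
#'
#' @param csf_nde,csf_de Monocular CSFs ([csf_params()] or profile).
#' @param binocular Binocular sensitivity ([csf_params()] or
#'   `binocular_profile`).
#' @param spec A [psychometric_spec()].
#' @param n_frequencies Number of frequencies (default 1000).
#' @param freq_range Frequency range, cpd (default 0.64--41, the tested
#'   range).
#' @param order Combination order, `"mean_first"` (default) or
#'   `"frequency_first"`.
#' @return An object of class `detection_profile`: per-frequency
#'   thresholds and probabilities, the means `p_nde` / `p_de`, the
#'   `p_expected` from probability summation, and the `observed_p`
#'   criterion.
#' @export
detection_profile <- function(csf_nde, csf_de, binocular,
                              spec = calibrate_psychometric_slope(),
                              n_frequencies = 1000,
                              freq_range = c(0.64, 41),
                              order = c("mean_first", "frequency_first")) {
  order <- match.arg(order)
  f <- 10^seq(log10(freq_range[1]), log10(freq_range[2]),
              length.out = n_frequencies)
  tau_bin <- threshold_from_sensitivity(sensitivity_at(binocular, f))
  clamp <- function(p) pmin(1 - spec$lapse_rate, pmax(spec$guess_rate, p))
  p_nde_f <- clamp(psychometric_p(
    tau_bin, threshold_from_sensitivity(sensitivity_at(csf_nde, f)), spec))
  p_de_f <- clamp(psychometric_p(
    tau_bin, threshold_from_sensitivity(sensitivity_at(csf_de, f)), spec))
  p_nde <- mean(p_nde_f)
  p_de <- mean(p_de_f)
  p_expected <- if (order == "mean_first") {
    expected_binocular_probability(p_nde, p_de, spec$guess_rate)
  } else {
    mean(expected_binocular_probability(p_nde_f, p_de_f, spec$guess_rate))
  }
  structure(list(frequencies = f, threshold_contrast_log10 = tau_bin,
                 p_nde_f = p_nde_f, p_de_f = p_de_f,
                 p_nde = p_nde, p_de = p_de, p_expected = p_expected,
                 observed_p = criterion_probability(spec), order = order),
            class = "detection_profile")
}

#' @export
print.detection_profile <- function(x, ...) {
  cat(sprintf(
    "Detection profile (%d frequencies): P_NDE %.3f, P_DE %.3f, expected binocular %.3f vs observed %.3f\n",
    length(x$frequencies), x$p_nde, x$p_de, x$p_expected, x$observed_p))
  invisible(x)
}

#' Classify binocular combination against probability summation
#'
#' The observed binocular performance sits, by construction, at the
#' criterion probability. If the expected probability-summation value falls
#' below the criterion (minus tolerance), the eyes together beat
#' independent detectors: supra-summation. Above it, binocular vision is
#' worse than independent detection: sub-summation. In between:
#' consistent with probability summation.
#'
#' @param profile A [detection_profile()], or a numeric expected
#'   probability.
#' @param observed Observed binocular probability (default: the profile's
#'   criterion).
#' @param tolerance Classification half-band, probability units.
#' @return `"supra"`, `"consistent"` or `"sub"`.
#' @export
classify_summation <- function(profile, observed = NULL, tolerance = 0.01) {
  expected <- if (inherits(profile, "detection_profile")) profile$p_expected
              else as.numeric(profile)
  observed <- observed %||%
    (if (inherits(profile, "detection_profile")) profile$observed_p else 0.53)
  if (expected < observed - tolerance) "supra"
  else if (expected > observed + tolerance) "sub"
  else "consistent"
}

#' Group-level summation classification
#'
#' One-sample two-sided t-test of a group's expected binocular
#' probabilities against the observed criterion, combined with the
#' practical tolerance band: a group is `"supra"` (or `"sub"`) only when
#' the test rejects at `alpha` *and* the group mean lies below (above) the
#' band. Degenerate groups (no variance) are classified by the band alone.
#'
#' @param p_expected Numeric vector of per-observer expected probabilities.
#' @param observed Observed binocular probability criterion.
#' @param alpha Significance level.
#' @param tolerance Practical band, probability units.
#' @return A list: `classification`, `p_value`, `mean_expected`.
#' @export
classify_summation_group <- function(p_expected, observed = 0.53,
                                     alpha = 0.05, tolerance = 0.01) {
  m <- mean(p_expected)
  if (length(p_expected) < 2 || stats::sd(p_expected) == 0) {
    cls <- classify_summation(m, observed, tolerance)
    return(list(classification = cls, p_value = NA_real_, mean_expected = m))
  }
  tt <- stats::t.test(p_expected, mu = observed)
  cls <- if (tt$p.value < alpha && m < observed - tolerance) "supra"
         else if (tt$p.value < alpha && m > observed + tolerance) "sub"
         else "consistent"
  list(classification = cls, p_value = tt$p.value, mean_expected = m)
}
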