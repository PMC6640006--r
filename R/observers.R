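#' Binocular combination regimes
#'
#' How a synthetic observer's binocular sensitivity profile is derived from
#' the two monocular CSFs:
#' * `regime_supra(factor)` -- neural summation: binocular sensitivity is
#'   `factor` times the better eye's sensitivity at every frequency. The
#'   default 1.4 is the canonical 40% binocular advantage of normal vision.
#' * `regime_probability()` -- independent detectors: at each frequency the
#'   binocular threshold is the contrast at which the guessing-corrected
#'   probability summation of the two monocular psychometric functions
#'   reaches the detection criterion (root-found).
#' * `regime_sub(factor)` -- inhibitory combination: `factor < 1` times the
#'   better eye (default 0.85).
#'
#' @param factor Sensitivity scale factor.
#' @name binocular_regimes
NULL

#' @rdname binocular_regimes
#' @export
regime_supra <- function(factor = 1.4) {
  if (factor < 1) stop_domain("supra regime needs factor >= 1")
  structure(list(type = "supra", factor = factor), class = "binocular_regime")
}

#' @rdname binocular_regimes
#' @export
regime_probability <- function() {
  structure(list(type = "probability", factor = NA_real_),
            class = "binocular_regime")
}

#' @rdname binocular_regimes
#' @export
regime_sub <- function(factor = 0.85) {
  if (factor <= 0 || factor >= 1) stop_domain("sub regime needs 0 < factor < 1")
  structure(list(type = "sub", factor = factor), class = "binocular_regime")
}

#' Group specification for the synthetic cohort
#'
#' Population distributions, on log10 axes, of the four CSF parameters for
#' each eye, plus cohort structure (size, number of fusers) and the
#' binocular combination regime, possibly conditional on fusion ability.
#'
#' @param name Group label, e.g. `"AMB"`, `"SWA"`, `"NSC"`.
#' @param n_subjects Number of subjects (>= 1).
#' @param n_fusers Number of subjects able to fuse at the test distance
#'   (0..n_subjects); fuser flags are assigned exactly within a cohort.
#' @param nde,de Per-eye parameter distributions: named lists with entries
#'   `log_gain`, `log_freq`, `log_bw`, `log_trunc`, each `c(mean, sd)` on
#'   the log10 scale.
#' @param regime_fuser,regime_nonfuser [binocular_regimes] applied to
#'   fusing / non-fusing subjects.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(name, n_subjects, n_fusers, nde, de,
                       regime_fuser, regime_nonfuser = regime_fuser) {
  stopifnot(n_subjects >= 1, n_fusers >= 0, n_fusers <= n_subjects,
            inherits(regime_fuser, "binocular_regime"),
            inherits(regime_nonfuser, "binocular_regime"))
  check_eye <- function(eye) {
    stopifnot(all(c("log_gain", "log_freq", "log_bw", "log_trunc") %in% names(eye)))
    for (p in eye) stopifnot(length(p) == 2, p[2] >= 0)
  }
  check_eye(nde); check_eye(de)
  structure(list(name = name, n_subjects = n_subjects, n_fusers = n_fusers,
                 nde = nde, de = de, regime_fuser = regime_fuser,
                 regime_nonfuser = regime_nonfuser),
            class = "group_spec")
}

# --- calibration of the default cohort ------------------------------------
#
# Printed anchors: AMB monocular means (DE peak SF 3.89 cpd / log gain 1.89;
# NDE 1.94 cpd / 1.77), group AULCSF statistics (AMB NDE 0.99 +/- 0.467,
# AMB DE 1.68, NSC 1.65 +/- 0.147), group sizes 11/20/24 with 5/7/24
# fusers. Everything else is calibrated: truncation is fixed at the
# population-typical 0.5 log10 units, per-eye bandwidth solves the AULCSF
# mean anchor given the gain/frequency means, and the log-gain spread is
# tuned by Gauss-Hermite quadrature so the population AULCSF mean and SD hit
# the printed values despite the nonlinearity (clipping at 0) of the AULCSF
# functional.

aulcsf_of <- function(lg, lf0, bw, dl, lo = 1.5, hi = 18, n = 400) {
  x <- seq(log10(lo), log10(hi), length.out = n)
  lf <- matrix(x, length(lg), n, byrow = TRUE)
  parab <- lg - 4 * log10(2) * ((lf - lf0) / bw)^2
  y <- ifelse(lf < lf0 & parab < (lg - dl), lg - dl, parab)
  y[y < 0] <- 0
  dx <- x[2] - x[1]
  (rowSums(y) - (y[, 1] + y[, n]) / 2) * dx
}

# Gauss-Hermite nodes/weights for a standard normal (Golub-Welsch via the
# symmetric tridiagonal Jacobi matrix).
gauss_hermite_normal <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = sqrt(2) * e$values, w = e$vectors[1, ]^2)
}

# Mean and SD of AULCSF when log gain ~ N(mu, sigma) and log peak frequency
# ~ N(lf0, sd_freq), other params fixed: tensor Gauss-Hermite quadrature.
aulcsf_moments <- function(mu, sigma, lf0, sd_freq, bw, dl, gh_g, gh_f) {
  zg <- rep(gh_g$x, times = length(gh_f$x))
  zf <- rep(gh_f$x, each = length(gh_g$x))
  wq <- rep(gh_g$w, times = length(gh_f$x)) * rep(gh_f$w, each = length(gh_g$x))
  a <- aulcsf_of(mu + sigma * zg, lf0 + sd_freq * zf, bw, dl)
  m <- sum(wq * a)
  v <- sum(wq * (a - m)^2)
  c(mean = m, sd = sqrt(v))
}

# Solve (mu, sigma) of log gain so the AULCSF population mean and SD match
# the targets, accounting for the peak-frequency spread.
calibrate_gain <- function(target_mean, target_sd, lf0, sd_freq, bw, dl, mu0,
                           gh_g = gauss_hermite_normal(31),
                           gh_f = gauss_hermite_normal(13)) {
  sigma <- target_sd  # starting guess; refined by fixed-point iteration
  mu <- mu0
  for (iter in 1:40) {
    mu <- stats::uniroot(
      function(m) aulcsf_moments(m, sigma, lf0, sd_freq, bw, dl,
                                 gh_g, gh_f)[["mean"]] - target_mean,
      c(mu0 - 2, mu0 + 2), tol = 1e-10)$root
    sd_now <- aulcsf_moments(mu, sigma, lf0, sd_freq, bw, dl,
                             gh_g, gh_f)[["sd"]]
    if (abs(sd_now - target_sd) < 1e-6) break
    sigma <- sigma * max(0.2, min(5, target_sd / sd_now))
  }
  c(mu = mu, sigma = sigma)
}

calibration_cache <- new.env(parent = emptyenv())

default_calibration <- function() {
  if (!is.null(calibration_cache$specs)) return(calibration_cache$specs)
  dl <- 0.5                       # shared truncation, log10 units
  sd_bw <- 0.03; sd_trunc <- 0.03 # modest spreads: no printed group differences
  sd_freq <- 0.08
  solve_bw <- function(lg, lf0, target)
    stats::uniroot(function(b) aulcsf_of(lg, lf0, b, dl) - target,
                   c(0.25, 2.7), tol = 1e-10)$root
  # bandwidths from the deterministic AULCSF anchors at the parameter means
  bw_de <- solve_bw(1.89, log10(3.89), 1.68)
  bw_nde <- solve_bw(1.77, log10(1.94), 0.99)
  bw_nsc <- solve_bw(1.89, log10(3.89), 1.65)
  # gain distributions matching population AULCSF mean +/- SD
  g_de <- calibrate_gain(1.68, 0.147, log10(3.89), sd_freq, bw_de, dl, 1.89)
  g_nde <- calibrate_gain(0.99, 0.467, log10(1.94), sd_freq, bw_nde, dl, 1.77)
  g_nsc <- calibrate_gain(1.65, 0.147, log10(3.89), sd_freq, bw_nsc, dl, 1.89)
  eye <- function(g, lf0, bw) {
    list(log_gain = c(g[["mu"]], g[["sigma"]]),
         log_freq = c(lf0, sd_freq),
         log_bw = c(log10(bw), sd_bw),
         log_trunc = c(log10(dl), sd_trunc))
  }
  nsc_eye <- eye(g_nsc, log10(3.89), bw_nsc)
  calibration_cache$specs <- list(
    AMB = group_spec("AMB", 11, 5,
                     nde = eye(g_nde, log10(1.94), bw_nde),
                     de = eye(g_de, log10(3.89), bw_de),
                     regime_fuser = regime_probability(),
                     regime_nonfuser = regime_probability()),
    SWA = group_spec("SWA", 20, 7,
                     nde = nsc_eye, de = nsc_eye,
                     regime_fuser = regime_probability(),
                     regime_nonfuser = regime_sub()),
    NSC = group_spec("NSC", 24, 24,
                     nde = nsc_eye, de = nsc_eye,
                     regime_fuser = regime_supra(),
                     regime_nonfuser = regime_supra())
  )
  calibration_cache$specs
}

#' Default group specifications of the synthetic cohort
#'
#' Three groups with the structure of the clinical study: amblyopia
#' (`AMB`, n = 11, 5 fusers), strabismus without amblyopia (`SWA`, n = 20,
#' 7 fusers) and normally sighted controls (`NSC`, n = 24, all fusing).
#' AMB monocular means are the printed group values (peak frequency
#' 3.89 cpd dominant / 1.94 cpd non-dominant; log10 peak gain 1.89 / 1.77);
#' parameter spreads are calibrated so the population AULCSF distributions
#' match the reported 0.99 +/- 0.467 (AMB non-dominant eye) and
#' 1.65 +/- 0.147 (controls). Binocular regimes: controls combine
#' supra-additively (factor 1.4); amblyopes and fusing strabismics combine
#' as independent detectors (probability summation); non-fusing strabismics
#' combine sub-additively (factor 0.85).
#'
#' @return A named list of three [group_spec()] objects.
#' @export
default_group_specs <- function() default_calibration()

#' Sample one synthetic observer
#'
#' Draws each eye's CSF parameters independently from the group's
#' log-normal marginals (the two eyes are sampled independently), then
#' derives the binocular sensitivity profile under the regime for the
#' observer's fusion status.
#'
#' @param spec A [group_spec()].
#' @param psych A [psychometric_spec()] shared by generation and analysis;
#'   defaults to the slope calibrated to the 1.2x probability-summation
#'   gain ([calibrate_psychometric_slope()]).
#' @param fuses Logical; when `NULL`, drawn Bernoulli with probability
#'   `n_fusers / n_subjects` ([generate_cohort()] instead assigns exact
#'   counts).
#' @param subject_id Identifier stored on the observer.
#' @return An object of class `synthetic_observer` with fields `csf_nde`,
#'   `csf_de` ([csf_params()]), `csf_bin` (a `binocular_profile`), `fuses`,
#'   `group`, `psych`.
#' @export
sample_observer <- function(spec, psych = calibrate_psychometric_slope(),
                            fuses = NULL, subject_id = NA_character_) {
  stopifnot(inherits(spec, "group_spec"))
  draw_eye <- function(eye) {
    v <- unname(vapply(eye[c("log_gain", "log_freq", "log_bw", "log_trunc")],
                       function(p) stats::rnorm(1, p[1], p[2]), numeric(1)))
    csf_params(10^v[1], 10^v[2], 10^v[3], 10^v[4])
  }
  csf_nde <- draw_eye(spec$nde)
  csf_de <- draw_eye(spec$de)
  if (is.null(fuses))
    fuses <- stats::runif(1) < spec$n_fusers / spec$n_subjects
  regime <- if (fuses) spec$regime_fuser else spec$regime_nonfuser
  structure(list(subject_id = subject_id, group = spec$name, fuses = fuses,
                 csf_nde = csf_nde, csf_de = csf_de,
                 csf_bin = derive_binocular_csf(csf_nde, csf_de, regime, psych),
                 psych = psych),
            class = "synthetic_observer")
}

#' Derive the binocular sensitivity profile from two monocular CSFs
#'
#' Probability summation of two log-parabolas is not itself a log-parabola,
#' so the binocular profile is kept as a dense frequency-to-sensitivity
#' table plus the generating monocular pair and regime; [sensitivity_at()]
#' recomputes sensitivity exactly at arbitrary frequencies (no
#' interpolation). Under `regime_probability()` the per-frequency binocular
#' threshold is found by bisection on log10 contrast of the
#' guessing-corrected probability-summation equation at the criterion
#' probability (0.53 with the default spec).
#'
#' @param csf_nde,csf_de Monocular [csf_params()].
#' @param regime A [binocular_regimes] object.
#' @param spec A [psychometric_spec()] (used by the probability regime).
#' @param frequencies Frequencies of the stored table, cpd.
#' @return An object of class `binocular_profile`.
#' @export
derive_binocular_csf <- function(csf_nde, csf_de, regime,
                                 spec = calibrate_psychometric_slope(),
                                 frequencies = 10^seq(log10(0.64), log10(41),
                                                      length.out = 1000)) {
  stopifnot(inherits(regime, "binocular_regime"))
  prof <- structure(list(csf_nde = csf_nde, csf_de = csf_de, regime = regime,
                         spec = spec, frequencies = frequencies,
                         sensitivity = NULL),
                    class = "binocular_profile")
  prof$sensitivity <- sensitivity_at(prof, frequencies)
  prof
}

#' @export
sensitivity_at.binocular_profile <- function(object, f) {
  s_best <- pmax(sensitivity_at(object$csf_nde, f),
                 sensitivity_at(object$csf_de, f))
  r <- object$regime
  if (r$type %in% c("supra", "sub")) return(r$factor * s_best)
  # probability regime: bisection on log10 contrast, vectorised over f
  spec <- object$spec
  crit <- criterion_probability(spec)
  tau_n <- threshold_from_sensitivity(sensitivity_at(object$csf_nde, f))
  tau_d <- threshold_from_sensitivity(sensitivity_at(object$csf_de, f))
  comb <- function(lc) {
    expected_binocular_probability(psychometric_p(lc, tau_n, spec),
                                   psychometric_p(lc, tau_d, spec),
                                   guess = spec$guess_rate)
  }
  lo <- rep(-12, length(f)); hi <- rep(8, length(f))
  if (any(comb(lo) >= crit) || any(comb(hi) <= crit))
    stop_domain("probability-summation root not bracketed")
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    below <- comb(mid) < crit
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  sensitivity_from_threshold((lo + hi) / 2)
}

#' @export
print.binocular_profile <- function(x, ...) {
  cat(sprintf("Binocular profile (%s regime), %d tabulated frequencies %.3g-%.3g cpd\n",
              x$regime$type, length(x$frequencies), min(x$frequencies),
              max(x$frequencies)))
  invisible(x)
}

#' Least-squares log-parabola refit of a binocular profile
#'
#' For reporting only: fits [csf_params()] to the profile's tabulated log10
#' sensitivities by Nelder-Mead least squares on the log10 parameter scale.
#'
#' @param profile A `binocular_profile`.
#' @return A [csf_params()] object.
#' @export
refit_log_parabola <- function(profile) {
  stopifnot(inherits(profile, "binocular_profile"))
  f <- profile$frequencies
  y <- log10(profile$sensitivity)
  i0 <- which.max(y)
  start <- c(y[i0], log10(f[i0]), log10(0.6), log10(0.5))
  obj <- function(th) {
    p <- try(csf_params(10^th[1], 10^th[2], 10^th[3], 10^th[4]), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    sum((csf_log_sensitivity(f, p) - y)^2)
  }
  fit <- stats::optim(start, obj, control = list(maxit = 2000, reltol = 1e-12))
  csf_params(10^fit$par[1], 10^fit$par[2], 10^fit$par[3], 10^fit$par[4])
}

#' Simulate one 10-AFC response
#'
#' Bernoulli draw with success probability given by the psychometric
#' function under the tested condition's sensitivity profile. Uses the
#' current RNG stream (seed the session, not the response).
#'
#' @param observer A `synthetic_observer`.
#' @param condition `"NDE"`, `"DE"` or `"BIN"`.
#' @param stimulus List with `frequency` and `contrast`.
#' @return Logical: response correct?
#' @export
simulate_response <- function(observer, condition, stimulus) {
  p <- response_probability(stimulus, observer_csf(observer, condition),
                            observer$psych)
  stats::runif(1) < p
}

#' Condition-specific sensitivity profile of an observer
#'
#' @param observer A `synthetic_observer`.
#' @param condition `"NDE"`, `"DE"` or `"BIN"`.
#' @export
observer_csf <- function(observer, condition) {
  switch(match.arg(condition, c("NDE", "DE", "BIN")),
         NDE = observer$csf_nde, DE = observer$csf_de, BIN = observer$csf_bin)
}

#' Responder closure for [run_session()]
#'
#' @inheritParams observer_csf
#' @export
make_responder <- function(observer, condition) {
  force(observer); force(condition)
  function(stimulus) simulate_response(observer, condition, stimulus)
}

#' Generate a group-structured synthetic cohort
#'
#' Deterministic given `seed`. Within each group exactly `n_fusers`
#' randomly chosen subjects are fusers; subject identifiers are
#' `<GROUP>_<nn>`.
#'
#' @param specs List of [group_spec()]s (default [default_group_specs()]).
#' @param seed Integer seed.
#' @param psych Shared [psychometric_spec()].
#' @return An object of class `cohort`: list of observers plus the specs
#'   and seed used.
#' @export
generate_cohort <- function(specs = default_group_specs(), seed = 1,
                            psych = calibrate_psychometric_slope()) {
  observers <- with_seed(seed, {
    out <- list()
    for (spec in specs) {
      fuse <- rep(FALSE, spec$n_subjects)
      fuse[sample.int(spec$n_subjects, spec$n_fusers)] <- TRUE
      for (i in seq_len(spec$n_subjects)) {
        out[[length(out) + 1L]] <- sample_observer(
          spec, psych = psych, fuses = fuse[i],
          subject_id = sprintf("%s_%02d", spec$name, i))
      }
    }
    out
  })
  structure(list(observers = observers, specs = specs, seed = seed,
                 psych = psych),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  grp <- table(vapply(x$observers, `[[`, character(1), "group"))
  cat("Synthetic cohort:",
      paste(sprintf("%s n=%d", names(grp), as.integer(grp)), collapse = ", "),
      sprintf("(seed %s)\n", format(x$seed)))
  invisible(x)
}

#' Population prior over a parameter grid
#'
#' Builds an informative prior for rescoring recorded sessions: a mixture,
#' over all eye distributions of the supplied group specs (weighted by
#' group size), of independent normal densities on the log10 parameter
#' axes, blended with a uniform floor so that no grid node is excluded a
#' priori. Because one session in three is binocular -- and binocular
#' sensitivity runs above monocular sensitivity by up to the ~40% of normal
#' binocular summation -- the mixture also contains a gain-shifted copy of
#' every component (one third of the population weight) so that binocular
#' sessions are not shrunk towards the monocular population.
#'
#' @param grid A [qcsf_grid()].
#' @param specs List of [group_spec()]s.
#' @param uniform_mix Weight of the uniform component (0..1, default 0.1).
#' @param binocular_gain_shift Log10 gain shift of the binocular mixture
#'   components (default `log10(1.3)`, between the probability-summation
#'   and full binocular-summation gains).
#' @return A `qcsf_posterior` usable as a prior.
#' @export
population_prior <- function(grid, specs = default_group_specs(),
                             uniform_mix = 0.1,
                             binocular_gain_shift = log10(1.3)) {
  stopifnot(uniform_mix >= 0, uniform_mix <= 1)
  nodes <- grid_nodes(grid)
  dens <- numeric(nrow(nodes))
  total_n <- sum(vapply(specs, `[[`, numeric(1), "n_subjects"))
  for (spec in specs) {
    for (eye in list(spec$nde, spec$de)) {
      base <- stats::dnorm(nodes[, "peak_frequency"], eye$log_freq[1],
                           max(eye$log_freq[2], 1e-6)) *
        stats::dnorm(nodes[, "bandwidth"], eye$log_bw[1],
                     max(eye$log_bw[2], 1e-6)) *
        stats::dnorm(nodes[, "truncation"], eye$log_trunc[1],
                     max(eye$log_trunc[2], 1e-6))
      g_mono <- stats::dnorm(nodes[, "peak_gain"], eye$log_gain[1],
                             max(eye$log_gain[2], 1e-6))
      g_bin <- stats::dnorm(nodes[, "peak_gain"],
                            eye$log_gain[1] + binocular_gain_shift,
                            max(eye$log_gain[2], 1e-6))
      dens <- dens + (spec$n_subjects / (2 * total_n)) *
        base * (2 / 3 * g_mono + 1 / 3 * g_bin)
    }
  }
  w <- (1 - uniform_mix) * dens / sum(dens) + uniform_mix / nrow(nodes)
  init_prior(grid, w)
}

#' Ground-truth manifest of a cohort
#'
#' One row per observer: group, fusion flag, the four CSF parameters of
#' each eye, and ground-truth AULCSF for the three viewing conditions.
#'
#' @param cohort A [generate_cohort()] result.
#' @param f_lo,f_hi AULCSF bounds, cpd.
#' @return A data frame.
#' @export
cohort_manifest <- function(cohort, f_lo = 1.5, f_hi = 18) {
  rows <- lapply(cohort$observers, function(ob) {
    data.frame(
      subject_id = ob$subject_id, group = ob$group, fuses = as.integer(ob$fuses),
      nde_peak_gain = ob$csf_nde$peak_gain,
      nde_peak_frequency = ob$csf_nde$peak_frequency,
      nde_bandwidth = ob$csf_nde$bandwidth,
      nde_truncation = ob$csf_nde$truncation,
      de_peak_gain = ob$csf_de$peak_gain,
      de_peak_frequency = ob$csf_de$peak_frequency,
      de_bandwidth = ob$csf_de$bandwidth,
      de_truncation = ob$csf_de$truncation,
      aulcsf_nde = aulcsf(ob$csf_nde, f_lo, f_hi),
      aulcsf_de = aulcsf(ob$csf_de, f_lo, f_hi),
      aulcsf_bin = aulcsf(ob$csf_bin, f_lo, f_hi),
      regime = ob$csf_bin$regime$type
    )
  })
  do.call(rbind, rows)
}
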