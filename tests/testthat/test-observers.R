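test_that("default group specs carry the clinical cohort structure", {
  specs <- default_group_specs()
  expect_named(specs, c("AMB", "SWA", "NSC"))
  expect_equal(vapply(specs, `[[`, numeric(1), "n_subjects"),
               c(AMB = 11, SWA = 20, NSC = 24))
  expect_equal(vapply(specs, `[[`, numeric(1), "n_fusers"),
               c(AMB = 5, SWA = 7, NSC = 24))
  # printed monocular means: peak frequency 3.89 / 1.94 cpd
  expect_equal(10^specs$AMB$de$log_freq[1], 3.89)
  expect_equal(10^specs$AMB$nde$log_freq[1], 1.94)
  # control regime: 40% supra-summation; patients: probability summation;
  # non-fusing strabismics: inhibition
  expect_equal(specs$NSC$regime_fuser$factor, 1.4)
  expect_equal(specs$AMB$regime_fuser$type, "probability")
  expect_equal(specs$SWA$regime_nonfuser$type, "sub")
})

test_that("group AULCSF calibration reproduces the printed population statistics", {
  specs <- default_group_specs()
  set.seed(20)
  draw_aulcsf <- function(eye, n) {
    g <- rnorm(n, eye$log_gain[1], eye$log_gain[2])
    f <- rnorm(n, eye$log_freq[1], eye$log_freq[2])
    b <- rnorm(n, eye$log_bw[1], eye$log_bw[2])
    tr <- rnorm(n, eye$log_trunc[1], eye$log_trunc[2])
    vapply(seq_len(n), function(i)
      aulcsf(csf_params(10^g[i], 10^f[i], 10^b[i], 10^tr[i]), n_points = 200),
      numeric(1))
  }
  a_amb <- draw_aulcsf(specs$AMB$nde, 5000)
  a_nsc <- draw_aulcsf(specs$NSC$nde, 5000)
  expect_equal(mean(a_amb), 0.99, tolerance = 0.02)
  expect_equal(mean(a_nsc), 1.65, tolerance = 0.02)
  # spreads within 10% of the printed SDs
  expect_equal(sd(a_amb), 0.467, tolerance = 0.1)
  expect_equal(sd(a_nsc), 0.147, tolerance = 0.1)
  a_de <- draw_aulcsf(specs$AMB$de, 5000)
  expect_equal(mean(a_de), 1.68, tolerance = 0.02)
})

test_that("zero-spread specs give deterministic observers at the means", {
  spec <- delta_spec(regime = regime_supra(1.4))
  set.seed(21)
  ob <- sample_observer(spec, psych = study_psych(), fuses = TRUE)
  expect_equal(ob$csf_nde$peak_gain, 10^1.89)
  expect_equal(ob$csf_nde$peak_frequency, 3.89)
  expect_equal(ob$csf_de$bandwidth, 0.613)
  set.seed(21)
  ob2 <- sample_observer(spec, psych = study_psych(), fuses = TRUE)
  expect_equal(ob$csf_nde, ob2$csf_nde)
})

test_that("sampled parameters converge to the spec marginals", {
  spec <- default_group_specs()$AMB
  set.seed(22)
  n <- 10000
  lf <- rnorm(n, spec$nde$log_freq[1], spec$nde$log_freq[2])
  se <- spec$nde$log_freq[2] / sqrt(n)
  expect_lt(abs(mean(lf) - log10(1.94)), 3 * se)
  # and through the observer sampler itself at smaller n
  sup <- delta_spec(regime = regime_supra(1.4))
  sup$nde$log_freq <- c(log10(1.94), 0.08)
  set.seed(23)
  m <- 400
  lfs <- replicate(m, log10(sample_observer(sup, psych = study_psych(),
                                            fuses = TRUE)$csf_nde$peak_frequency))
  expect_lt(abs(mean(lfs) - log10(1.94)), 3 * 0.08 / sqrt(m))
})

test_that("supra and sub regimes scale the better eye; identity at factor 1", {
  psych <- study_psych()
  a <- csf_params(80, 3, 0.6, 0.5)
  b <- csf_params(40, 2, 0.7, 0.4)
  f <- 10^seq(log10(0.64), log10(41), length.out = 50)
  sup <- derive_binocular_csf(a, b, regime_supra(1.4), psych)
  expect_equal(sensitivity_at(sup, f),
               1.4 * pmax(sensitivity_at(a, f), sensitivity_at(b, f)))
  sub <- derive_binocular_csf(a, b, regime_sub(0.85), psych)
  expect_true(all(sensitivity_at(sub, f) <
                    pmax(sensitivity_at(a, f), sensitivity_at(b, f))))
  ident <- derive_binocular_csf(a, a, regime_supra(1), psych)
  expect_equal(sensitivity_at(ident, f), sensitivity_at(a, f))
})

test_that("probability summation of identical eyes matches the root-search oracle", {
  psych <- study_psych()
  a <- csf_params(80, 3, 0.6, 0.5)
  prof <- derive_binocular_csf(a, a, regime_probability(), psych)
  crit <- criterion_probability(psych)
  f <- c(1, 3, 10, 25)
  s_bin <- sensitivity_at(prof, f)
  for (i in seq_along(f)) {
    tau <- threshold_from_sensitivity(csf_sensitivity(f[i], a))
    g <- function(lc) expected_binocular_probability(
      psychometric_p(lc, tau, psych), psychometric_p(lc, tau, psych), 0.1) - crit
    root <- uniroot(g, c(tau - 3, tau + 3), tol = 1e-13)$root
    expect_equal(s_bin[i], sensitivity_from_threshold(root), tolerance = 1e-8)
    # the equal-eye probability-summation gain is the calibrated 1.2
    expect_equal(s_bin[i] / csf_sensitivity(f[i], a), 1.2, tolerance = 1e-6)
  }
  # probability summation never falls below the better eye
  ff <- 10^seq(log10(0.64), log10(41), length.out = 30)
  b <- csf_params(15, 1.8, 0.55, 0.5)
  pab <- derive_binocular_csf(a, b, regime_probability(), psych)
  expect_true(all(sensitivity_at(pab, ff) >=
                    pmax(sensitivity_at(a, ff), sensitivity_at(b, ff)) - 1e-9))
})

test_that("a functionally blind eye adds nothing under probability summation", {
  psych <- study_psych()
  good <- csf_params(80, 3, 0.6, 0.5)
  blind <- csf_params(1.0001, 3, 0.6, 0.5)
  prof <- derive_binocular_csf(blind, good, regime_probability(), psych)
  f <- c(1, 3, 8)
  expect_equal(sensitivity_at(prof, f), sensitivity_at(good, f),
               tolerance = 0.02)
})

test_that("stored binocular tables regenerate exactly from the monocular pair", {
  psych <- study_psych()
  a <- csf_params(60, 2.5, 0.6, 0.5)
  b <- csf_params(90, 4, 0.65, 0.45)
  for (reg in list(regime_supra(1.4), regime_probability(), regime_sub(0.85))) {
    prof <- derive_binocular_csf(a, b, reg, psych, frequencies = 10^seq(-0.19, 1.6, length.out = 80))
    again <- derive_binocular_csf(prof$csf_nde, prof$csf_de, prof$regime, prof$spec,
                                  frequencies = prof$frequencies)
    expect_identical(prof$sensitivity, again$sensitivity)
  }
})

test_that("simulated responses are Bernoulli with the psychometric probability", {
  psych <- study_psych()
  spec <- delta_spec(regime = regime_supra(1.4))
  set.seed(24)
  ob <- sample_observer(spec, psych = psych, fuses = TRUE)
  n <- 10000
  # at the dominant-eye threshold contrast for a mid frequency
  tau <- threshold_from_sensitivity(csf_sensitivity(4, ob$csf_de))
  stim <- list(frequency = 4, contrast = 10^tau)
  set.seed(25)
  hits <- mean(replicate(n, simulate_response(ob, "DE", stim)))
  expect_lt(abs(hits - 0.53), 3 * sqrt(0.53 * 0.47 / n))
  # far below threshold: guessing floor
  stim_lo <- list(frequency = 4, contrast = 10^(tau - 2))
  set.seed(26)
  miss <- mean(replicate(n, simulate_response(ob, "DE", stim_lo)))
  expect_lt(abs(miss - 0.1), 3 * sqrt(0.1 * 0.9 / n))
  # reproducible stream
  set.seed(27); r1 <- replicate(20, simulate_response(ob, "BIN", stim))
  set.seed(27); r2 <- replicate(20, simulate_response(ob, "BIN", stim))
  expect_identical(r1, r2)
})

test_that("cohort generation is exact in structure and deterministic in seed", {
  c1 <- generate_cohort(seed = 31)
  groups <- vapply(c1$observers, `[[`, character(1), "group")
  fuses <- vapply(c1$observers, `[[`, logical(1), "fuses")
  expect_equal(length(c1$observers), 55)
  expect_equal(as.vector(table(groups)[c("AMB", "SWA", "NSC")]), c(11, 20, 24))
  expect_equal(sum(fuses[groups == "AMB"]), 5)
  expect_equal(sum(fuses[groups == "SWA"]), 7)
  expect_equal(sum(fuses[groups == "NSC"]), 24)
  c2 <- generate_cohort(seed = 31)
  expect_equal(cohort_manifest(c1), cohort_manifest(c2))
  c3 <- generate_cohort(seed = 32)
  expect_false(isTRUE(all.equal(cohort_manifest(c1)$nde_peak_gain,
                                cohort_manifest(c3)$nde_peak_gain)))
})

test_that("population prior is a proper distribution concentrated on the population", {
  g <- small_grid()
  prior <- population_prior(g)
  expect_equal(sum(prior$w), 1, tolerance = 1e-12)
  expect_true(all(prior$w > 0))
  nodes <- grid_nodes(g)
  near <- which.min((nodes[, "peak_gain"] - 1.89)^2 +
                      (nodes[, "peak_frequency"] - log10(3.89))^2 +
                      (nodes[, "bandwidth"] - log10(0.613))^2 +
                      (nodes[, "truncation"] - log10(0.5))^2)
  far <- which.max(nodes[, "peak_gain"] - nodes[, "peak_frequency"])
  expect_gt(prior$w[near], prior$w[far])
})
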