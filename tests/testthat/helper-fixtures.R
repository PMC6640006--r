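# Shared fixtures: small grids and observers used across test files.

tiny_grid <- function() {
  qcsf_grid(gain_range = c(5, 500), gain_n = 3,
            freq_range = c(0.5, 10), freq_n = 3,
            bw_range = c(0.4, 1.2), bw_n = 2,
            trunc_range = c(0.1, 1), trunc_n = 2)
}

small_grid <- function() {
  qcsf_grid(gain_range = c(2, 2000), gain_n = 8,
            freq_range = c(0.3, 16), freq_n = 6,
            bw_range = c(0.35, 1.6), bw_n = 4,
            trunc_range = c(0.05, 1.5), trunc_n = 4)
}

small_space <- function() {
  stimulus_space(freq_n = 8, contrast_n = 10)
}

# an NSC-like ground truth observer CSF
nsc_truth <- function() csf_params(10^1.89, 3.89, 0.613, 0.5)

# zero-spread group spec with configurable eyes/regime, for deterministic
# observers
delta_spec <- function(log_gain_nde = 1.89, log_gain_de = 1.89,
                       lf_nde = log10(3.89), lf_de = log10(3.89),
                       bw = 0.613, trunc = 0.5,
                       regime = regime_probability(),
                       n_subjects = 4, n_fusers = 2) {
  eye <- function(lg, lf) list(log_gain = c(lg, 0), log_freq = c(lf, 0),
                               log_bw = c(log10(bw), 0),
                               log_trunc = c(log10(trunc), 0))
  group_spec("TST", n_subjects, n_fusers,
             nde = eye(log_gain_nde, lf_nde), de = eye(log_gain_de, lf_de),
             regime_fuser = regime, regime_nonfuser = regime)
}

study_psych <- function() calibrate_psychometric_slope()
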