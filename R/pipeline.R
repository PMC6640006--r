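#' Configuration of an end-to-end synthetic study
#'
#' Bundles the cohort specification, engine settings, analysis settings and
#' FPR settings behind one master seed. The default engine grid and
#' stimulus space are deliberately coarser than the standalone engine
#' defaults so that a full study (55 subjects x 3 conditions x 25 trials)
#' runs in well under a minute; grid resolution mainly adds precision to
#' single-session estimates and is configurable.
#'
#' @param groups List of [group_spec()]s.
#' @param grid A [qcsf_grid()] for the adaptive engine.
#' @param select_grid Coarser companion grid for stimulus selection (see
#'   [run_session()]'s `select_cache`), or `NULL` to select on the full
#'   grid.
#' @param space A [stimulus_space()].
#' @param psych A [psychometric_spec()] shared by simulation and analysis.
#' @param n_trials Trials per session (25 in the tablet protocol).
#' @param aulcsf_range AULCSF integration bounds, cpd.
#' @param n_profile_frequencies Frequencies of the detection profile.
#' @param classification_tolerance Band for [classify_summation()].
#' @param alpha Significance level of the group tests.
#' @param fpr An [fpr_config()], or `NULL` to skip the FPR stage.
#' @param rescore Rescore every recorded session with the cohort
#'   [population_prior()] before analysis, as in the tablet protocol
#'   (recording runs under a uniform prior). Markedly reduces
#'   single-session estimation noise.
#' @param master_seed Master integer seed; all stage seeds derive from it.
#' @param output_dir Directory for the CSV bundle, or `NULL` to skip
#'   writing.
#' @return An object of class `study_config`.
#' @export
study_config <- function(groups = default_group_specs(),
                         grid = qcsf_grid(gain_n = 28, freq_n = 22,
                                          bw_n = 12, trunc_n = 12),
                         select_grid = qcsf_grid(gain_n = 10, freq_n = 8,
                                                 bw_n = 6, trunc_n = 5),
                         space = stimulus_space(freq_n = 20, contrast_n = 25),
                         psych = calibrate_psychometric_slope(),
                         n_trials = 25,
                         aulcsf_range = c(1.5, 18),
                         n_profile_frequencies = 1000,
                         classification_tolerance = 0.01,
                         alpha = 0.05,
                         fpr = fpr_config(),
                         rescore = FALSE,
                         master_seed = 1,
                         output_dir = NULL) {
  stopifnot(n_trials >= 0, length(aulcsf_range) == 2, alpha > 0, alpha < 1)
  structure(list(groups = groups, grid = grid, select_grid = select_grid,
                 space = space, psych = psych,
                 n_trials = n_trials, aulcsf_range = aulcsf_range,
                 n_profile_frequencies = n_profile_frequencies,
                 classification_tolerance = classification_tolerance,
                 alpha = alpha, fpr = fpr, rescore = rescore,
                 master_seed = master_seed, output_dir = output_dir),
            class = "study_config")
}

#' Run a full synthetic replication of the study
#'
#' Generates the cohort, runs one adaptive session per subject and viewing
#' condition (non-dominant eye, dominant eye, binocular; condition order
#' randomised per subject), computes per-subject estimates and the
#' binocular summation analysis from the *estimated* CSFs, and aggregates
#' group statistics: summation-index tests against unity, group-level
#' classification against probability summation (overall and split by
#' fusion ability for the patient groups), and the false-positive-risk
#' simulation anchored at the study's own AMB-vs-NSC AULCSF comparison.
#' Fully deterministic given `config$master_seed`.
#'
#' @param config A [study_config()].
#' @param quiet Suppress stage progress messages.
#' @param engine_cache,selection_cache Optional prebuilt [qcsf_cache()]s
#'   matching `config$grid` / `config$select_grid`; building the engine
#'   cache dominates start-up cost, so callers running many seeded studies
#'   under one configuration should build the caches once and pass them in.
#' @return An object of class `study_report`.
#' @export
run_study <- function(config = study_config(), quiet = TRUE,
                      engine_cache = NULL, selection_cache = NULL) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  seed0 <- config$master_seed

  say("stage cohort: seed %d", derive_seed(seed0, 1))
  cohort <- generate_cohort(config$groups, seed = derive_seed(seed0, 1),
                            psych = config$psych)
  manifest <- cohort_manifest(cohort, config$aulcsf_range[1],
                              config$aulcsf_range[2])

  say("stage engine cache: %d nodes x %d stimuli",
      n_nodes(config$grid), nrow(config$space))
  cache <- engine_cache %||%
    qcsf_cache(config$grid, config$space, config$psych,
               aulcsf_range = config$aulcsf_range)
  if (nrow(cache$lik) != n_nodes(config$grid))
    stop_domain("engine_cache does not match config$grid")
  pop_prior <- if (isTRUE(config$rescore))
    population_prior(config$grid, config$groups) else NULL
  sel_cache <- if (!is.null(selection_cache)) selection_cache
    else if (!is.null(config$select_grid))
      qcsf_cache(config$select_grid, config$space, config$psych,
                 aulcsf_range = config$aulcsf_range) else NULL
  if (!is.null(sel_cache) && nrow(sel_cache$lik) != n_nodes(config$select_grid))
    stop_domain("selection_cache does not match config$select_grid")

  conditions <- c("NDE", "DE", "BIN")
  est_rows <- list()
  trial_rows <- list()
  sess_i <- 0L
  for (i in seq_along(cohort$observers)) {
    ob <- cohort$observers[[i]]
    order_i <- with_seed(derive_seed(seed0, 1000 + i),
                         sample(conditions))
    for (cond in order_i) {
      sess_i <- sess_i + 1L
      ses <- run_session(make_responder(ob, cond), config$n_trials,
                         cache = cache, seed = derive_seed(seed0, 2000 + sess_i),
                         select_cache = sel_cache)
      if (!is.null(pop_prior)) {
        post <- reweight_posterior(ses$posterior, pop_prior)
        ses$posterior <- post
        ses$estimates <- posterior_estimates(post, cache = cache)
      }
      e <- ses$estimates
      est_rows[[sess_i]] <- data.frame(
        subject_id = ob$subject_id, condition = cond,
        peak_gain = e$params$peak_gain,
        peak_frequency_cpd = e$params$peak_frequency,
        bandwidth = e$params$bandwidth, truncation = e$params$truncation,
        aulcsf = e$aulcsf, csf_acuity_cpd = as.numeric(e$csf_acuity),
        ci_width_683 = e$ci_width_683)
      trial_rows[[sess_i]] <- data.frame(
        subject_id = ob$subject_id, condition = cond,
        trial_index = ses$trials$trial_index,
        frequency_cpd = ses$trials$frequency,
        contrast = ses$trials$contrast,
        correct = as.integer(ses$trials$correct))
    }
  }
  estimates <- do.call(rbind, est_rows)
  trial_log <- do.call(rbind, trial_rows)

  say("stage summation analysis: %d subjects", length(cohort$observers))
  summation <- summation_table(cohort, estimates, config)

  say("stage group statistics")
  tests <- group_tests(summation, config)

  fpr_res <- NULL
  if (!is.null(config$fpr)) {
    say("stage FPR")
    fpr_res <- study_fpr(estimates, manifest, config)
  }

  report <- structure(list(
    config = config, manifest = manifest, estimates = estimates,
    trial_log = trial_log, summation = summation, tests = tests,
    group_summary = group_summary(estimates, manifest, summation),
    fpr = fpr_res,
    classification_tally = table(factor(summation$classification,
                                        c("supra", "consistent", "sub")),
                                 summation$group)),
    class = "study_report")
  if (!is.null(config$output_dir)) write_study_report(report, config$output_dir)
  report
}

# Per-subject summation analysis from the estimated CSFs.
summation_table <- function(cohort, estimates, config) {
  rows <- lapply(cohort$observers, function(ob) {
    e <- estimates[estimates$subject_id == ob$subject_id, ]
    get <- function(cond) {
      r <- e[e$condition == cond, ]
      list(params = csf_params(r$peak_gain, r$peak_frequency_cpd,
                               r$bandwidth, r$truncation),
           aulcsf = r$aulcsf)
    }
    nde <- get("NDE"); de <- get("DE"); bin <- get("BIN")
    prof <- detection_profile(nde$params, de$params, bin$params,
                              spec = config$psych,
                              n_frequencies = config$n_profile_frequencies)
    data.frame(subject_id = ob$subject_id, group = ob$group,
               fuses = as.integer(ob$fuses),
               aulcsf_nde = nde$aulcsf, aulcsf_de = de$aulcsf,
               aulcsf_bin = bin$aulcsf,
               summation_index = summation_index(bin$aulcsf, de$aulcsf),
               p_nde = prof$p_nde, p_de = prof$p_de,
               p_expected = prof$p_expected,
               classification = classify_summation(
                 prof, tolerance = config$classification_tolerance))
  })
  do.call(rbind, rows)
}

# Group statistics: summation index vs 1 and classification vs probability
# summation, for the subgroups reported by the study.
group_tests <- function(summation, config) {
  subsets <- list(
    AMB = summation$group == "AMB",
    AMB_fusers = summation$group == "AMB" & summation$fuses == 1,
    SWA = summation$group == "SWA",
    SWA_fusers = summation$group == "SWA" & summation$fuses == 1,
    SWA_nonfusers = summation$group == "SWA" & summation$fuses == 0,
    NSC = summation$group == "NSC")
  out <- lapply(names(subsets), function(nm) {
    s <- summation[subsets[[nm]], ]
    if (nrow(s) < 2) return(NULL)
    idx <- summation_vs_unity_test(s$summation_index)
    cls <- classify_summation_group(s$p_expected, observed = 0.53,
                                    alpha = config$alpha,
                                    tolerance = config$classification_tolerance)
    data.frame(subset = nm, n = nrow(s),
               mean_index = idx$mean_index, index_p = idx$p_value,
               index_gt_1 = idx$mean_index > 1 &
                 !is.na(idx$p_value) & idx$p_value < config$alpha,
               mean_p_expected = cls$mean_expected,
               summation_p = cls$p_value,
               classification = cls$classification)
  })
  do.call(rbind, out)
}

# FPR anchored at this study's own AMB-NDE vs NSC-NDE AULCSF comparison.
study_fpr <- function(estimates, manifest, config) {
  amb <- merge(estimates[estimates$condition == "NDE", ],
               manifest[, c("subject_id", "group")], by = "subject_id")
  a <- amb$aulcsf[amb$group == "AMB"]
  n <- amb$aulcsf[amb$group == "NSC"]
  if (length(a) < 2 || length(n) < 2) return(NULL)
  obs <- stats::t.test(a, n)
  cfg <- config$fpr
  observed_p <- min(max(obs$p.value, 1e-12), 0.5)
  res <- fpr_simulation(fpr_config(
    null_mean = mean(n), null_sd = stats::sd(n),
    alt_mean = mean(a), alt_sd = stats::sd(a),
    n_test = length(a), n_ref = length(n),
    n_sim = cfg$n_sim, observed_p = observed_p,
    band_factor = cfg$band_factor,
    seed = derive_seed(config$master_seed, 99)))
  list(observed_p = obs$p.value, result = res)
}

group_summary <- function(estimates, manifest, summation) {
  est <- merge(estimates, manifest[, c("subject_id", "group")],
               by = "subject_id")
  agg <- stats::aggregate(
    cbind(peak_gain, peak_frequency_cpd, bandwidth, truncation, aulcsf,
          csf_acuity_cpd, ci_width_683) ~ group + condition,
    data = est, FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  idx <- stats::aggregate(summation_index ~ group, data = summation,
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  list(estimates = agg, summation_index = idx)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Synthetic study report: %d subjects, %d sessions of %d trials\n",
              nrow(x$manifest), nrow(x$estimates), x$config$n_trials))
  cat("\nGroup tests:\n")
  print(x$tests, row.names = FALSE, digits = 3)
  if (!is.null(x$fpr)) {
    cat(sprintf("\nAMB-NDE vs NSC-NDE AULCSF: observed p = %.3g; FPR = %.4g\n",
                x$fpr$observed_p, x$fpr$result$fpr))
  }
  invisible(x)
}

#' Qualitative study pattern
#'
#' Extracts, from a [run_study()] report, the qualitative findings the
#' clinical study reports: controls show supra-summation, amblyopes and
#' fusing strabismics are consistent with probability summation, non-fusing
#' strabismics show sub-summation, the control summation index exceeds 1,
#' and the amblyopic index does not differ from 1.
#'
#' @param report A `study_report`.
#' @return A named logical vector.
#' @export
study_pattern <- function(report) {
  t <- report$tests
  g <- function(nm, col) t[t$subset == nm, col]
  c(nsc_supra = g("NSC", "classification") == "supra",
    amb_consistent = g("AMB", "classification") == "consistent",
    swa_fusers_consistent = g("SWA_fusers", "classification") == "consistent",
    swa_nonfusers_sub = g("SWA_nonfusers", "classification") == "sub",
    nsc_index_gt_1 = g("NSC", "index_gt_1"),
    amb_index_not_gt_1 = !g("AMB", "index_gt_1"))
}

# --- file formats ----------------------------------------------------------

#' Trial-log CSV
#'
#' One row per trial: `subject_id`, `condition` (NDE/DE/BIN),
#' `trial_index`, `frequency_cpd`, `contrast`, `correct` (0/1). UTF-8,
#' header row, '.' decimal separator. Unknown extra columns are preserved
#' on reading; malformed rows raise an error naming the row.
#'
#' @param trials Data frame in the schema above.
#' @param path CSV path.
#' @export
write_trial_log <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "condition", "trial_index", "frequency_cpd",
            "contrast", "correct")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_domain("trial log missing column(s): ", paste(miss, collapse = ", "))
  bad_row <- function(cond, what) {
    i <- which(cond)[1]
    stop_domain("trial log row ", i, ": ", what)
  }
  if (nrow(x)) {
    if (any(!x$condition %in% c("NDE", "DE", "BIN")))
      bad_row(!x$condition %in% c("NDE", "DE", "BIN"), "unknown condition")
    if (any(!is.finite(x$contrast) | x$contrast <= 0 | x$contrast > 1))
      bad_row(!is.finite(x$contrast) | x$contrast <= 0 | x$contrast > 1,
              "contrast must be in (0, 1]")
    if (any(!is.finite(x$frequency_cpd) | x$frequency_cpd <= 0))
      bad_row(!is.finite(x$frequency_cpd) | x$frequency_cpd <= 0,
              "frequency must be > 0")
    if (any(!x$correct %in% c(0, 1)))
      bad_row(!x$correct %in% c(0, 1), "correct must be 0 or 1")
  }
  x
}

#' Write the study's CSV bundle
#'
#' Writes `trial_log.csv`, `estimates.csv`, `summation.csv`,
#' `manifest.csv`, `group_tests.csv`, and (when present) `fpr.txt` into
#' `dir`.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trial_log(report$trial_log, file.path(dir, "trial_log.csv"))
  utils::write.csv(report$estimates, file.path(dir, "estimates.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summation, file.path(dir, "summation.csv"),
                   row.names = FALSE)
  utils::write.csv(report$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(report$tests, file.path(dir, "group_tests.csv"),
                   row.names = FALSE)
  if (!is.null(report$fpr))
    write_fpr_report(report$fpr$result, file.path(dir, "fpr.txt"))
  invisible(dir)
}

# --- plain key=value configuration -----------------------------------------

config_registry <- c(
  "master_seed", "n_trials", "alpha", "classification_tolerance",
  "n_profile_frequencies", "aulcsf_lo", "aulcsf_hi",
  "grid_gain_n", "grid_freq_n", "grid_bw_n", "grid_trunc_n",
  "stim_freq_n", "stim_contrast_n",
  "summation_gain", "fpr_n_sim", "fpr_band_factor", "fpr_observed_p",
  "output_dir")

#' Parse a plain key=value study configuration file
#'
#' Blank lines and `#` comments are ignored; absent keys take their
#' defaults; unknown keys raise an error listing the valid keys (no silent
#' typos). Numeric values are converted; `output_dir` stays a string.
#'
#' @param path Path to the config file.
#' @return A [study_config()].
#' @export
parse_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop_domain("malformed config line: '", ln, "' (expected key=value)")
    key <- trimws(parts[1]); val <- trimws(parts[2])
    if (!key %in% config_registry)
      stop_domain("unknown config key '", key, "'; valid keys: ",
                  paste(config_registry, collapse = ", "))
    kv[[key]] <- val
  }
  num <- function(key, default) {
    if (is.null(kv[[key]])) default else as.numeric(kv[[key]])
  }
  grid <- qcsf_grid(gain_n = num("grid_gain_n", 28),
                    freq_n = num("grid_freq_n", 22),
                    bw_n = num("grid_bw_n", 12),
                    trunc_n = num("grid_trunc_n", 12))
  space <- stimulus_space(freq_n = num("stim_freq_n", 20),
                          contrast_n = num("stim_contrast_n", 25))
  study_config(
    grid = grid, space = space,
    psych = calibrate_psychometric_slope(num("summation_gain", 1.2)),
    n_trials = num("n_trials", 25),
    aulcsf_range = c(num("aulcsf_lo", 1.5), num("aulcsf_hi", 18)),
    n_profile_frequencies = num("n_profile_frequencies", 1000),
    classification_tolerance = num("classification_tolerance", 0.01),
    alpha = num("alpha", 0.05),
    fpr = fpr_config(n_sim = num("fpr_n_sim", 100000),
                     band_factor = num("fpr_band_factor", 2),
                     observed_p = num("fpr_observed_p", 0.0009)),
    master_seed = num("master_seed", 1),
    output_dir = kv[["output_dir"]])
}
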