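#' Parameter grid for the adaptive engine
#'
#' Log-spaced axes over the four CSF parameters. The posterior lives on the
#' Cartesian product of the axes, enumerated with `peak_gain` varying
#' fastest, then `peak_frequency`, `bandwidth`, `truncation` (the
#' [expand.grid()] order). Axis ranges follow published CSF population
#' ranges; the bandwidth axis spans 1--9 octaves expressed in the
#' log10-frequency units of the model (`1 octave = log10(2)` units).
#'
#' @param gain_range,gain_n Peak-gain axis: range (linear sensitivity) and
#'   number of log-spaced nodes.
#' @param freq_range,freq_n Peak-frequency axis (cpd).
#' @param bw_range,bw_n Bandwidth axis (log10-frequency units).
#' @param trunc_range,trunc_n Truncation axis (log10-sensitivity units).
#' @return An object of class `qcsf_grid`.
#' @export
qcsf_grid <- function(gain_range = c(2, 2000), gain_n = 30,
                      freq_range = c(0.2, 20), freq_n = 25,
                      bw_range = c(1, 9) * log10(2), bw_n = 15,
                      trunc_range = c(0.02, 2), trunc_n = 15) {
  axis <- function(range, n, name) {
    if (length(range) != 2 || range[1] <= 0 || range[2] <= range[1] || n < 2)
      stop_domain("invalid axis for ", name)
    10^seq(log10(range[1]), log10(range[2]), length.out = n)
  }
  axes <- list(
    peak_gain = axis(gain_range, gain_n, "peak_gain"),
    peak_frequency = axis(freq_range, freq_n, "peak_frequency"),
    bandwidth = axis(bw_range, bw_n, "bandwidth"),
    truncation = axis(trunc_range, trunc_n, "truncation")
  )
  structure(list(axes = axes), class = "qcsf_grid")
}

#' @export
print.qcsf_grid <- function(x, ...) {
  n <- vapply(x$axes, length, integer(1))
  cat(sprintf("qCSF parameter grid: %s = %d nodes\n",
              paste(n, collapse = " x "), prod(n)))
  invisible(x)
}

#' Grid nodes as a log10 parameter matrix
#'
#' One row per node, columns `peak_gain`, `peak_frequency`, `bandwidth`,
#' `truncation`, all log10-transformed, in the documented enumeration order.
#'
#' @param grid A [qcsf_grid()].
#' @export
grid_nodes <- function(grid) {
  stopifnot(inherits(grid, "qcsf_grid"))
  g <- expand.grid(lapply(grid$axes, log10), KEEP.OUT.ATTRS = FALSE)
  as.matrix(g)
}

n_nodes <- function(grid) prod(vapply(grid$axes, length, integer(1)))

#' Initialise a posterior over the parameter grid
#'
#' @param grid A [qcsf_grid()].
#' @param weights `NULL` for a uniform prior, or non-negative weights (one
#'   per grid node, in enumeration order; an array with dimensions matching
#'   the axis lengths is also accepted). Weights are normalised to sum to 1.
#' @return An object of class `qcsf_posterior` with fields `grid` and `w`.
#' @export
init_prior <- function(grid, weights = NULL) {
  stopifnot(inherits(grid, "qcsf_grid"))
  n <- n_nodes(grid)
  if (is.null(weights)) {
    w <- rep(1 / n, n)
  } else {
    w <- as.numeric(weights)
    if (length(w) != n)
      stop_domain("weights length ", length(w), " does not match grid size ", n)
    if (any(!is.finite(w)) || any(w < 0))
      stop_domain("weights must be finite and non-negative")
    s <- sum(w)
    if (s <= 0) stop_domain("weights sum to zero: no valid distribution")
    w <- w / s
  }
  structure(list(grid = grid, w = w), class = "qcsf_posterior")
}

#' @export
print.qcsf_posterior <- function(x, ...) {
  cat(sprintf("qCSF posterior over %d nodes (entropy %.2f bits)\n",
              length(x$w), posterior_entropy(x)))
  invisible(x)
}

#' Shannon entropy of a posterior, in bits
#'
#' @param posterior A `qcsf_posterior`.
#' @export
posterior_entropy <- function(posterior) {
  w <- posterior$w[posterior$w > 0]
  -sum(w * log2(w))
}

#' Discrete stimulus space for the letter task
#'
#' Log-spaced spatial frequencies crossed with log-spaced Michelson
#' contrasts. Rows are ordered by contrast (slow) then frequency (fast),
#' ascending, which fixes the deterministic tie-break of
#' [select_stimulus()]: among equal-information stimuli the lowest contrast
#' wins, then the lowest frequency.
#'
#' @param freq_range,freq_n Frequency axis in cpd (default 0.64--41, the
#'   tested letter range).
#' @param contrast_range,contrast_n Contrast axis in (0, 1].
#' @return A data frame with columns `frequency` and `contrast`, of class
#'   `stimulus_space`.
#' @export
stimulus_space <- function(freq_range = c(0.64, 41), freq_n = 30,
                           contrast_range = c(0.001, 1), contrast_n = 40) {
  if (any(freq_range <= 0) || any(contrast_range <= 0) || max(contrast_range) > 1)
    stop_domain("frequencies must be > 0 and contrasts in (0, 1]")
  f <- 10^seq(log10(freq_range[1]), log10(freq_range[2]), length.out = freq_n)
  ct <- 10^seq(log10(contrast_range[1]), log10(contrast_range[2]),
               length.out = contrast_n)
  out <- expand.grid(frequency = f, contrast = ct, KEEP.OUT.ATTRS = FALSE)
  class(out) <- c("stimulus_space", "data.frame")
  out
}

# Log10 sensitivity of every grid node at each frequency.
# nodes: log10 parameter matrix; returns length(nodes rows) x length(f).
node_log_sensitivity <- function(nodes, f) {
  lg <- nodes[, "peak_gain"]
  lf0 <- nodes[, "peak_frequency"]
  bw <- 10^nodes[, "bandwidth"]
  dl <- 10^nodes[, "truncation"]
  plateau <- lg - dl
  out <- matrix(0, nrow(nodes), length(f))
  for (j in seq_along(f)) {
    lf <- log10(f[j])
    parab <- lg - 4 * log10(2) * ((lf - lf0) / bw)^2
    out[, j] <- ifelse(lf < lf0 & parab < plateau, plateau, parab)
  }
  out
}

#' Probability of a correct response to a stimulus, given CSF parameters
#'
#' Evaluates the psychometric function at the stimulus contrast with the
#' threshold set by the CSF: `tau = -log10 S(frequency)`.
#'
#' @param stimulus A list or one-row data frame with `frequency` (cpd) and
#'   `contrast` (Michelson, in (0, 1]).
#' @param params A [csf_params()] object (or anything with a
#'   [sensitivity_at()] method).
#' @param spec A [psychometric_spec()].
#' @export
response_probability <- function(stimulus, params, spec = psychometric_spec()) {
  S <- sensitivity_at(params, stimulus$frequency)
  psychometric_p(log10(stimulus$contrast), threshold_from_sensitivity(S), spec)
}

#' Precomputed session cache
#'
#' The per-trial work of the engine reduces to matrix-vector products
#' against a node-by-stimulus likelihood matrix. This helper builds that
#' matrix, its binary entropies, and the per-node AULCSF used for posterior
#' summaries, so the expensive parts are shared across the many sessions of
#' a simulated study.
#'
#' @param grid A [qcsf_grid()].
#' @param space A [stimulus_space()].
#' @param spec A [psychometric_spec()].
#' @param aulcsf_range Bounds for the per-node AULCSF summary, cpd.
#' @param aulcsf_points Trapezoid nodes for the per-node AULCSF.
#' @return An object of class `qcsf_cache`.
#' @export
qcsf_cache <- function(grid, space = stimulus_space(),
                       spec = psychometric_spec(),
                       aulcsf_range = c(1.5, 18), aulcsf_points = 120) {
  nodes <- grid_nodes(grid)
  fu <- sort(unique(space$frequency))
  ls_f <- node_log_sensitivity(nodes, fu)      # nodes x unique freqs
  k <- spec$k
  lo <- spec$guess_rate
  span <- 1 - spec$guess_rate - spec$lapse_rate
  lik <- matrix(0, nrow(nodes), nrow(space))
  fidx <- match(space$frequency, fu)
  lc <- log10(space$contrast)
  for (j in seq_len(nrow(space))) {
    # c - tau = log10 contrast + log10 S(f)
    lik[, j] <- lo + span * stats::pnorm(k * (lc[j] + ls_f[, fidx[j]]))
  }
  # per-node AULCSF by accumulation (keeps memory flat for large grids)
  x <- seq(log10(aulcsf_range[1]), log10(aulcsf_range[2]),
           length.out = aulcsf_points)
  dx <- x[2] - x[1]
  A <- numeric(nrow(nodes))
  lsa <- node_log_sensitivity(nodes, 10^x)
  for (j in seq_len(aulcsf_points)) {
    wgt <- if (j == 1L || j == aulcsf_points) dx / 2 else dx
    A <- A + wgt * pmax(0, lsa[, j])
  }
  structure(list(grid = grid, space = space, spec = spec,
                 lik = lik, lik_ent = cbind(lik, binary_entropy(lik)),
                 node_aulcsf = A, aulcsf_range = aulcsf_range),
            class = "qcsf_cache")
}

#' Expected information gain of a stimulus
#'
#' Mutual information, in bits, between the Bernoulli response to a
#' candidate stimulus and the CSF parameters under the current posterior:
#' `H(p_bar) - sum_theta w(theta) H(p(theta))`, where `p_bar` is the
#' posterior-predictive probability correct and `H` is the binary entropy.
#' Non-negative; zero when the likelihood is constant over the posterior's
#' support.
#'
#' @param posterior A `qcsf_posterior`.
#' @param stimulus A list with `frequency` and `contrast`.
#' @param spec A [psychometric_spec()].
#' @export
expected_information_gain <- function(posterior, stimulus,
                                      spec = psychometric_spec()) {
  nodes <- grid_nodes(posterior$grid)
  ls <- node_log_sensitivity(nodes, stimulus$frequency)[, 1]
  p <- spec$guess_rate + (1 - spec$guess_rate - spec$lapse_rate) *
    stats::pnorm(spec$k * (log10(stimulus$contrast) + ls))
  w <- posterior$w
  max(0, binary_entropy(sum(w * p)) - sum(w * binary_entropy(p)))
}

# Batch information gain over all cached stimuli: one matrix-vector product
# against [lik | H(lik)] yields the predictive probability and the expected
# response entropy for every stimulus at once.
information_gain_batch <- function(w, cache) {
  m <- ncol(cache$lik)
  v <- drop(crossprod(cache$lik_ent, w))
  pmax(0, binary_entropy(v[seq_len(m)]) - v[m + seq_len(m)])
}

#' Select the most informative stimulus
#'
#' Arg-max of [expected_information_gain()] over the discrete stimulus
#' space. Deterministic: ties go to the lowest contrast, then the lowest
#' frequency (the row order of [stimulus_space()]).
#'
#' @param posterior A `qcsf_posterior`.
#' @param space A [stimulus_space()]; ignored when `cache` is given.
#' @param spec A [psychometric_spec()]; ignored when `cache` is given.
#' @param cache Optional [qcsf_cache()] congruent with the posterior's grid.
#' @return A list with `frequency`, `contrast`, `index` (row in the space),
#'   and `gain` (bits).
#' @export
select_stimulus <- function(posterior, space = NULL,
                            spec = psychometric_spec(), cache = NULL) {
  if (is.null(cache)) {
    if (is.null(space) || nrow(space) == 0) stop_domain("empty stimulus space")
    cache <- qcsf_cache(posterior$grid, space, spec)
  }
  gains <- information_gain_batch(posterior$w, cache)
  i <- which(gains >= max(gains) - 1e-15)[1]
  list(frequency = cache$space$frequency[i], contrast = cache$space$contrast[i],
       index = i, gain = gains[i])
}

#' Bayes update of the posterior after one trial
#'
#' Multiplies the weights by the Bernoulli likelihood of the observed
#' response under every grid node and renormalises.
#'
#' @param posterior A `qcsf_posterior`.
#' @param trial A list with `stimulus` (frequency, contrast) and `correct`
#'   (logical).
#' @param spec A [psychometric_spec()].
#' @param lik_col Optional precomputed per-node probability-correct vector
#'   for the trial's stimulus (column of a cache's likelihood matrix).
#' @export
update_posterior <- function(posterior, trial, spec = psychometric_spec(),
                             lik_col = NULL) {
  if (is.null(lik_col)) {
    nodes <- grid_nodes(posterior$grid)
    ls <- node_log_sensitivity(nodes, trial$stimulus$frequency)[, 1]
    lik_col <- spec$guess_rate + (1 - spec$guess_rate - spec$lapse_rate) *
      stats::pnorm(spec$k * (log10(trial$stimulus$contrast) + ls))
  }
  L <- if (isTRUE(trial$correct)) lik_col else 1 - lik_col
  w <- posterior$w * L
  s <- sum(w)
  if (s <= 0) stop_domain("degenerate update: likelihood is zero everywhere")
  posterior$w <- w / s
  posterior
}

#' Posterior summaries: parameter estimates, AULCSF, acuity, CI width
#'
#' Parameter estimates are posterior means taken on the log10 axes (all
#' axes are log-spaced). The AULCSF estimate is the posterior-weighted mean
#' of the per-node AULCSF; its 68.3% credible-interval width (the distance
#' between the 0.1585 and 0.8415 weighted quantiles of the node AULCSF
#' distribution) serves as a test-retest variability proxy. CSF acuity is
#' evaluated at the posterior-mean parameters.
#'
#' @param posterior A `qcsf_posterior`.
#' @param cache Optional [qcsf_cache()] holding per-node AULCSF values.
#' @param aulcsf_range,aulcsf_points AULCSF bounds/resolution when no cache
#'   is supplied.
#' @return A list: `params` ([csf_params()]), `aulcsf`, `csf_acuity`,
#'   `ci_width_683`.
#' @export
posterior_estimates <- function(posterior, cache = NULL,
                                aulcsf_range = c(1.5, 18),
                                aulcsf_points = 120) {
  nodes <- grid_nodes(posterior$grid)
  w <- posterior$w
  m <- drop(crossprod(nodes, w))
  params <- csf_params(10^m[["peak_gain"]], 10^m[["peak_frequency"]],
                       10^m[["bandwidth"]], 10^m[["truncation"]])
  if (is.null(cache)) {
    x <- seq(log10(aulcsf_range[1]), log10(aulcsf_range[2]),
             length.out = aulcsf_points)
    lsa <- node_log_sensitivity(nodes, 10^x)
    lsa[lsa < 0] <- 0
    dx <- x[2] - x[1]
    wt <- rep(dx, aulcsf_points); wt[c(1, aulcsf_points)] <- dx / 2
    A <- drop(lsa %*% wt)
  } else {
    A <- cache$node_aulcsf
  }
  q <- weighted_quantile(A, w, c(0.1585, 0.8415))
  list(params = params,
       aulcsf = sum(w * A),
       csf_acuity = csf_acuity(params),
       ci_width_683 = q[2] - q[1])
}

#' Run one adaptive quick CSF session
#'
#' Alternates information-maximising stimulus selection, a response from
#' the observer, and a Bayes update, for `n_trials` trials (25 in the
#' tablet protocol). The observer is any function mapping a stimulus (list
#' with `frequency`, `contrast`) to a logical correct/incorrect; simulated
#' observers draw their response from the session's seeded RNG stream, so a
#' given seed reproduces the session bit for bit.
#'
#' @param responder `function(stimulus) -> logical`.
#' @param n_trials Number of trials (>= 0).
#' @param prior A `qcsf_posterior` (default: uniform on the cache's grid).
#' @param cache A [qcsf_cache()]; build one with the grid, stimulus space
#'   and psychometric spec of the experiment.
#' @param seed Integer seed for the session (optional). The caller's RNG
#'   state is restored afterwards.
#' @param select_cache Optional second [qcsf_cache()] over a coarser grid
#'   but the *same* stimulus space and spec. When given, stimulus selection
#'   runs on a companion coarse posterior while Bayes updates and estimates
#'   stay on the fine grid -- the expected-information-gain surface is flat
#'   near its optimum, so selection loses almost nothing from coarse
#'   resolution while the per-trial cost drops by orders of magnitude.
#' @return An object of class `qcsf_session`: `trials` (data frame with
#'   `trial_index`, `frequency`, `contrast`, `correct`), `posterior`, and
#'   `estimates` (see [posterior_estimates()]).
#' @export
run_session <- function(responder, n_trials = 25, prior = NULL, cache,
                        seed = NULL, select_cache = NULL) {
  stopifnot(inherits(cache, "qcsf_cache"), is.function(responder))
  if (n_trials < 0) stop_domain("n_trials must be >= 0")
  post <- prior %||% init_prior(cache$grid)
  if (length(post$w) != nrow(cache$lik))
    stop_domain("prior grid does not match cache grid")
  if (!is.null(select_cache)) {
    if (!isTRUE(all.equal(select_cache$space, cache$space)) ||
        !identical(select_cache$spec$k, cache$spec$k))
      stop_domain("select_cache must share the cache's stimulus space and spec")
    post_sel <- init_prior(select_cache$grid)
  }
  trials <- data.frame(trial_index = integer(0), frequency = numeric(0),
                       contrast = numeric(0), correct = logical(0))
  with_seed(seed, {
    for (t in seq_len(n_trials)) {
      sel <- if (is.null(select_cache)) select_stimulus(post, cache = cache)
             else select_stimulus(post_sel, cache = select_cache)
      stim <- list(frequency = sel$frequency, contrast = sel$contrast)
      ok <- isTRUE(responder(stim))
      trial <- list(stimulus = stim, correct = ok)
      post <- update_posterior(post, trial, spec = cache$spec,
                               lik_col = cache$lik[, sel$index])
      if (!is.null(select_cache))
        post_sel <- update_posterior(post_sel, trial, spec = cache$spec,
                                     lik_col = select_cache$lik[, sel$index])
      trials[t, ] <- list(t, stim$frequency, stim$contrast, ok)
    }
  })
  structure(list(trials = trials, posterior = post,
                 estimates = posterior_estimates(post, cache = cache)),
            class = "qcsf_session")
}

#' @export
print.qcsf_session <- function(x, ...) {
  e <- x$estimates
  cat(sprintf(
    "qCSF session: %d trials; AULCSF %.3f (68.3%% CI width %.3f); peak gain %.3g; acuity %.3g cpd\n",
    nrow(x$trials), e$aulcsf, e$ci_width_683, e$params$peak_gain,
    as.numeric(e$csf_acuity)))
  invisible(x)
}

#' Reweight a posterior under a different prior
#'
#' Bayes' rule factorises the posterior into prior times likelihood, so a
#' session recorded under `old_prior` can be rescored under `new_prior` by
#' elementwise reweighting -- no replay of the trials is needed:
#' `w_new ~ w * new_prior / old_prior`. With the default uniform
#' `old_prior` this is simply a product with the new prior's weights.
#' Exactly equivalent to [rescore_session()] on the recorded trials.
#'
#' @param posterior A `qcsf_posterior` obtained under `old_prior`.
#' @param new_prior The informative prior to impose.
#' @param old_prior The prior the posterior was computed under (default
#'   uniform).
#' @export
reweight_posterior <- function(posterior, new_prior, old_prior = NULL) {
  if (length(posterior$w) != length(new_prior$w))
    stop_domain("prior grid does not match posterior grid")
  w <- posterior$w * new_prior$w
  if (!is.null(old_prior)) {
    if (any(old_prior$w <= 0))
      stop_domain("old_prior must have full support")
    w <- w / old_prior$w
  }
  s <- sum(w)
  if (s <= 0) stop_domain("degenerate reweighting: no overlapping support")
  posterior$w <- w / s
  posterior
}

#' Rescore recorded trials under a different prior
#'
#' Replays the Bayes updates of a completed session, in trial order, on a
#' new prior (typically a more informative population prior). Stimulus
#' selection is not re-run: the recorded stimuli are taken as given.
#'
#' @param trials Data frame with `frequency`, `contrast`, `correct` (the
#'   `trials` component of a [run_session()] result, or a read trial log).
#' @param prior A `qcsf_posterior` supplying grid and starting weights.
#' @param spec A [psychometric_spec()].
#' @param cache Optional congruent [qcsf_cache()] (used only for the
#'   AULCSF node values in the estimates).
#' @return A `qcsf_session` (with the supplied trials).
#' @export
rescore_session <- function(trials, prior, spec = psychometric_spec(),
                            cache = NULL) {
  stopifnot(inherits(prior, "qcsf_posterior"))
  if (!is.null(cache) && length(prior$w) != nrow(cache$lik))
    stop_domain("prior grid does not match cache grid")
  post <- prior
  nodes <- grid_nodes(prior$grid)
  span <- 1 - spec$guess_rate - spec$lapse_rate
  for (i in seq_len(nrow(trials))) {
    ls <- node_log_sensitivity(nodes, trials$frequency[i])[, 1]
    p <- spec$guess_rate + span *
      stats::pnorm(spec$k * (log10(trials$contrast[i]) + ls))
    post <- update_posterior(
      post,
      list(stimulus = list(frequency = trials$frequency[i],
                           contrast = trials$contrast[i]),
           correct = trials$correct[i]),
      spec = spec, lik_col = p)
  }
  structure(list(trials = trials, posterior = post,
                 estimates = posterior_estimates(post, cache = cache)),
            class = "qcsf_session")
}
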