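test_that("prior initialisation normalises and validates weights", {
  g <- tiny_grid()              # 3 x 3 x 2 x 2 = 36 nodes
  u <- init_prior(g)
  expect_equal(u$w, rep(1 / 36, 36))
  w <- runif(36)
  p <- init_prior(g, w)
  expect_equal(p$w, w / sum(w))
  expect_equal(sum(p$w), 1, tolerance = 1e-12)
  expect_error(init_prior(g, rep(0, 36)), "zero")
  expect_error(init_prior(g, rep(1, 10)), "does not match")
})

test_that("grid nodes enumerate the Cartesian product in documented order", {
  g <- tiny_grid()
  nodes <- grid_nodes(g)
  expect_equal(nrow(nodes), 36)
  # peak_gain varies fastest
  expect_equal(unname(nodes[1:3, "peak_gain"]), log10(g$axes$peak_gain))
  expect_equal(nodes[1, "peak_frequency"], nodes[3, "peak_frequency"])
  expect_equal(unname(nodes[4, "peak_frequency"]), log10(g$axes$peak_frequency[2]))
})

test_that("expected information gain matches an exhaustive two-outcome oracle", {
  spec <- study_psych()
  g <- tiny_grid()
  set.seed(10)
  for (i in 1:10) {
    post <- init_prior(g, runif(36)^2)
    stim <- list(frequency = 10^runif(1, -0.1, 1.5),
                 contrast = 10^runif(1, -2.5, 0))
    # oracle: H(prior) minus expected posterior entropy over both outcomes
    nodes <- grid_nodes(g)
    p <- vapply(seq_len(36), function(j) {
      th <- csf_params(10^nodes[j, 1], 10^nodes[j, 2], 10^nodes[j, 3],
                       10^nodes[j, 4])
      response_probability(stim, th, spec)
    }, numeric(1))
    pbar <- sum(post$w * p)
    ent <- function(w) { w <- w[w > 0]; -sum(w * log2(w)) }
    w_c <- post$w * p / pbar
    w_i <- post$w * (1 - p) / (1 - pbar)
    ig_oracle <- ent(post$w) - (pbar * ent(w_c) + (1 - pbar) * ent(w_i))
    expect_equal(expected_information_gain(post, stim, spec), ig_oracle,
                 tolerance = 1e-9)
  }
})

test_that("information gain is zero for point posteriors and flat likelihoods", {
  g <- tiny_grid()
  spec <- study_psych()
  w <- rep(0, 36); w[17] <- 1
  post <- init_prior(g, w)
  expect_equal(expected_information_gain(
    post, list(frequency = 4, contrast = 0.05), spec), 0)
  # far-above-cutoff stimulus: every node answers at the guessing floor
  post2 <- init_prior(g)
  ig <- expected_information_gain(
    post2, list(frequency = 1e5, contrast = 1e-6), spec)
  expect_equal(ig, 0, tolerance = 1e-10)
})

test_that("stimulus selection is the exhaustive argmax with documented tie-break", {
  spec <- study_psych()
  g <- tiny_grid()
  space <- small_space()
  cache <- qcsf_cache(g, space, spec)
  set.seed(11)
  post <- init_prior(g, runif(36))
  sel <- select_stimulus(post, cache = cache)
  gains <- vapply(seq_len(nrow(space)), function(j)
    expected_information_gain(post, list(frequency = space$frequency[j],
                                         contrast = space$contrast[j]), spec),
    numeric(1))
  expect_equal(sel$gain, max(gains), tolerance = 1e-12)
  expect_equal(sel$index, which.max(gains))
  # single-stimulus space returns that stimulus
  one <- stimulus_space(freq_range = c(4, 4.0001), freq_n = 2,
                        contrast_range = c(0.1, 0.100001), contrast_n = 2)
  sel1 <- select_stimulus(post, space = one[1, , drop = FALSE], spec = spec)
  expect_equal(sel1$frequency, 4)
  # degenerate point-mass posterior: all gains zero, tie-break picks the
  # lowest contrast, then the lowest frequency (row 1)
  wpt <- rep(0, 36); wpt[5] <- 1
  selt <- select_stimulus(init_prior(g, wpt), cache = cache)
  expect_equal(selt$index, 1L)
  expect_equal(selt$contrast, min(space$contrast))
  expect_equal(selt$frequency, min(space$frequency))
})

test_that("posterior updates follow Bayes rule and stay normalised", {
  spec <- study_psych()
  g <- tiny_grid()
  post <- init_prior(g, runif(36))
  t1 <- list(stimulus = list(frequency = 3, contrast = 0.02), correct = TRUE)
  t2 <- list(stimulus = list(frequency = 8, contrast = 0.2), correct = FALSE)
  p1 <- update_posterior(post, t1, spec)
  p12 <- update_posterior(p1, t2, spec)
  expect_equal(sum(p1$w), 1, tolerance = 1e-12)
  expect_equal(sum(p12$w), 1, tolerance = 1e-12)
  # two sequential updates equal one update with the product likelihood
  nodes <- grid_nodes(g)
  lik_of <- function(tr) {
    p <- vapply(seq_len(36), function(j) {
      th <- csf_params(10^nodes[j, 1], 10^nodes[j, 2], 10^nodes[j, 3],
                       10^nodes[j, 4])
      response_probability(tr$stimulus, th, spec)
    }, numeric(1))
    if (tr$correct) p else 1 - p
  }
  w_direct <- post$w * lik_of(t1) * lik_of(t2)
  expect_equal(p12$w, w_direct / sum(w_direct), tolerance = 1e-12)
  # flat likelihood leaves the posterior unchanged
  flat <- update_posterior(post, t1, spec, lik_col = rep(0.4, 36))
  expect_equal(flat$w, post$w, tolerance = 1e-14)
  expect_error(update_posterior(post, t1, spec, lik_col = rep(0, 36)),
               "degenerate")
})

test_that("a correct response at low contrast cannot lower the gain estimate", {
  spec <- study_psych()
  g <- small_grid()
  post <- init_prior(g)
  nodes <- grid_nodes(g)
  mean_lg <- function(p) sum(p$w * nodes[, "peak_gain"])
  tr <- list(stimulus = list(frequency = 4, contrast = 0.002), correct = TRUE)
  expect_gte(mean_lg(update_posterior(post, tr, spec)), mean_lg(post))
})

test_that("posterior estimates match point-mass and weighted-quantile oracles", {
  spec <- study_psych()
  g <- tiny_grid()
  cache <- qcsf_cache(g, small_space(), spec)
  nodes <- grid_nodes(g)
  # point mass: estimates equal that node, CI width 0
  w <- rep(0, 36); w[23] <- 1
  est <- posterior_estimates(init_prior(g, w), cache = cache)
  expect_equal(log10(est$params$peak_gain), unname(nodes[23, "peak_gain"]))
  expect_equal(est$aulcsf, cache$node_aulcsf[23])
  expect_equal(est$ci_width_683, 0)
  # two equally weighted nodes: AULCSF estimate is the mean
  w2 <- rep(0, 36); w2[c(3, 30)] <- 0.5
  est2 <- posterior_estimates(init_prior(g, w2), cache = cache)
  expect_equal(est2$aulcsf, mean(cache$node_aulcsf[c(3, 30)]))
  # random posterior: CI width against an independent weighted-quantile scan
  set.seed(12)
  wr <- runif(36); wr <- wr / sum(wr)
  estr <- posterior_estimates(init_prior(g, wr), cache = cache)
  o <- order(cache$node_aulcsf)
  a_s <- cache$node_aulcsf[o]; w_s <- cumsum(wr[o])
  q <- function(pr) a_s[which(w_s >= pr - 1e-12)[1]]
  expect_equal(estr$ci_width_683, q(0.8415) - q(0.1585))
})

test_that("sessions are reproducible and a zero-trial session returns the prior", {
  spec <- study_psych()
  cache <- qcsf_cache(small_grid(), small_space(), spec)
  truth <- nsc_truth()
  resp <- function(stim) runif(1) < response_probability(stim, truth, spec)
  s1 <- run_session(resp, 25, cache = cache, seed = 42)
  s2 <- run_session(resp, 25, cache = cache, seed = 42)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$estimates, s2$estimates)
  s3 <- run_session(resp, 25, cache = cache, seed = 43)
  expect_false(identical(s1$trials, s3$trials))
  s0 <- run_session(resp, 0, cache = cache, seed = 1)
  expect_equal(s0$estimates, posterior_estimates(init_prior(cache$grid),
                                                 cache = cache))
})

test_that("coarse-grid stimulus selection preserves the fine-grid posterior contract", {
  spec <- study_psych()
  cache <- qcsf_cache(small_grid(), small_space(), spec)
  sel_cache <- qcsf_cache(tiny_grid(), small_space(), spec)
  truth <- nsc_truth()
  resp <- function(stim) runif(1) < response_probability(stim, truth, spec)
  s <- run_session(resp, 15, cache = cache, seed = 5, select_cache = sel_cache)
  expect_equal(sum(s$posterior$w), 1, tolerance = 1e-12)
  # the fine posterior must equal a replay of the recorded trials
  replay <- rescore_session(s$trials, init_prior(cache$grid), spec = spec,
                            cache = cache)
  expect_equal(s$posterior$w, replay$posterior$w, tolerance = 1e-12)
  expect_error(run_session(resp, 5, cache = cache, seed = 1,
                           select_cache = qcsf_cache(tiny_grid(),
                                                     stimulus_space(freq_n = 5,
                                                                    contrast_n = 5),
                                                     spec)),
               "stimulus space")
})

test_that("average posterior entropy never exceeds prior entropy at the chosen stimulus", {
  spec <- study_psych()
  g <- tiny_grid()
  cache <- qcsf_cache(g, small_space(), spec)
  set.seed(13)
  for (i in 1:5) {
    post <- init_prior(g, runif(36)^2)
    sel <- select_stimulus(post, cache = cache)
    p <- cache$lik[, sel$index]
    pbar <- sum(post$w * p)
    stim <- list(frequency = sel$frequency, contrast = sel$contrast)
    h_c <- posterior_entropy(update_posterior(post, list(stimulus = stim, correct = TRUE), spec,
                                              lik_col = p))
    h_i <- posterior_entropy(update_posterior(post, list(stimulus = stim, correct = FALSE), spec,
                                              lik_col = p))
    expect_lte(pbar * h_c + (1 - pbar) * h_i,
               posterior_entropy(post) + 1e-12)
  }
})

test_that("rescoring replays trials exactly and reweighting is equivalent", {
  spec <- study_psych()
  g <- small_grid()
  cache <- qcsf_cache(g, small_space(), spec)
  truth <- nsc_truth()
  resp <- function(stim) runif(1) < response_probability(stim, truth, spec)
  ses <- run_session(resp, 20, cache = cache, seed = 9)
  # rescoring with the original (uniform) prior reproduces the posterior
  re_u <- rescore_session(ses$trials, init_prior(g), spec = spec, cache = cache)
  expect_equal(re_u$posterior$w, ses$posterior$w, tolerance = 1e-12)
  # empty trial list returns the prior unchanged
  empty <- ses$trials[0, ]
  pr <- init_prior(g, runif(prod(vapply(g$axes, length, integer(1)))))
  expect_equal(rescore_session(empty, pr, spec = spec)$posterior$w, pr$w)
  # reweighting shortcut equals a full replay under the informative prior
  pop <- population_prior(g)
  re_pop <- rescore_session(ses$trials, pop, spec = spec, cache = cache)
  rw <- reweight_posterior(ses$posterior, pop)
  expect_equal(rw$w, re_pop$posterior$w, tolerance = 1e-10)
  expect_error(rescore_session(ses$trials, init_prior(tiny_grid()),
                               spec = spec, cache = cache), "does not match")
})

test_that("credible-interval width shrinks as trials accumulate", {
  spec <- study_psych()
  cache <- qcsf_cache(small_grid(), small_space(), spec)
  truth <- nsc_truth()
  ci5 <- ci25 <- numeric(20)
  for (s in 1:20) {
    resp <- function(stim) runif(1) < response_probability(stim, truth, spec)
    ci5[s] <- run_session(resp, 5, cache = cache, seed = 300 + s)$estimates$ci_width_683
    ci25[s] <- run_session(resp, 25, cache = cache, seed = 300 + s)$estimates$ci_width_683
  }
  expect_lt(mean(ci25), mean(ci5))
})

test_that("an informative prior concentrated near truth improves short sessions", {
  spec <- study_psych()
  g <- small_grid()
  cache <- qcsf_cache(g, small_space(), spec)
  truth <- nsc_truth()
  a_true <- aulcsf(truth)
  nodes <- grid_nodes(g)
  near <- stats::dnorm(nodes[, "peak_gain"], log10(truth$peak_gain), 0.15) *
    stats::dnorm(nodes[, "peak_frequency"], log10(truth$peak_frequency), 0.15) *
    stats::dnorm(nodes[, "bandwidth"], log10(truth$bandwidth), 0.1) *
    stats::dnorm(nodes[, "truncation"], log10(truth$truncation), 0.1)
  pop <- init_prior(g, near / sum(near) + 1e-4)
  err_u <- err_p <- numeric(60)
  for (s in 1:60) {
    resp <- function(stim) runif(1) < response_probability(stim, truth, spec)
    ses <- run_session(resp, 10, cache = cache, seed = 100 + s)
    err_u[s] <- abs(ses$estimates$aulcsf - a_true)
    err_p[s] <- abs(posterior_estimates(reweight_posterior(ses$posterior, pop),
                                        cache = cache)$aulcsf - a_true)
  }
  expect_lt(median(err_p), median(err_u))
})
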