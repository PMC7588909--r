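test_that("softmax normalises, preserves order and is shift invariant", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(c(0, log(3))), c(0.25, 0.75))
  expect_equal(softmax(c(5, 5, 5)), softmax(c(0, 0, 0)))
  set.seed(42)
  for (i in 1:20) {
    x <- stats::rnorm(sample(2:8, 1))
    sc <- stats::runif(1, 0.1, 5)
    p <- softmax(x, scale = sc)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_identical(order(p), order(x))
    expect_equal(p, softmax(x + 3.7, scale = sc), tolerance = 1e-12)
  }
  expect_equal(softmax(c(1, 2), 2), softmax(c(101, 102), 2))
  expect_error(softmax(c(1, Inf)), "finite")
  expect_error(softmax(numeric(0)), "non-empty")
})

test_that("KL divergence matches closed forms and is zero iff equal", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-5)
  expect_equal(kl_divergence(c(0.7, 0.3), c(0.5, 0.5)), 0.0822829,
               tolerance = 1e-6)
  set.seed(7)
  for (i in 1:20) {
    q <- softmax(stats::rnorm(4))
    p <- softmax(stats::rnorm(4))
    expect_gte(kl_divergence(q, p), 0)
  }
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0, 0)), "mismatch")
})

test_that("free energy equals complexity minus accuracy and bounds surprise", {
  # flat likelihood: complexity 0, accuracy -log|O| regardless of states
  expect_equal(free_energy(c(0.5, 0.5), c(0.5, 0.5), c(1 / 4, 1 / 4)),
               log(4), tolerance = 1e-6)
  # direct evaluation of the two sums
  expect_equal(free_energy(c(0.7, 0.3), c(0.5, 0.5), c(0.9, 0.2)),
               0.6388667, tolerance = 1e-6)
  # tight at the exact posterior: F = -log P(o)
  prior <- c(0.4, 0.6)
  lik <- c(0.9, 0.2)
  post <- prior * lik / sum(prior * lik)
  expect_equal(free_energy(post, prior, lik), -log(sum(prior * lik)),
               tolerance = 1e-6)
  # any other q lies above the bound
  set.seed(11)
  for (i in 1:20) {
    q <- softmax(stats::rnorm(2))
    expect_gte(free_energy(q, prior, lik), -log(sum(prior * lik)) - 1e-8)
  }
  expect_error(free_energy(c(0.9, 0.3), prior, lik), "normalised")
})

test_that("flat likelihoods leave posteriors at the propagated priors", {
  m <- toy_model(seed = 3, flat_likelihood = TRUE)
  obs <- observation_set(m, x = c(1L, 1L), y = c(2L, 2L))
  bel <- infer_states(m, obs, policy = 1L)
  for (f in names(m$factors)) {
    expect_equal(bel$Q[[f]][, 1], m$D[[f]], tolerance = 1e-6,
                 ignore_attr = TRUE)
    prop <- as.vector(m$B[[f]][, , m$policies[1, f]] %*% m$D[[f]])
    expect_equal(bel$Q[[f]][, 2], prop, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("deterministic evidence concentrates the posterior", {
  m <- toy_model(seed = 5, deterministic = TRUE)
  # generate a consistent observation from the model's own deterministic maps
  s1 <- vapply(m$D, which.max, integer(1))
  o1 <- vapply(names(m$modalities), function(md)
    which.max(m$A[[md]][, s1[1], s1[2], s1[3]]), integer(1))
  obs <- observation_set(m, x = c(o1[["x"]], NA), y = c(o1[["y"]], NA))
  bel <- infer_states(m, obs, 1L)
  for (f in names(m$factors))
    expect_lt(.entropy_pub(bel$Q[[f]][, 1]), 1e-6)
})

test_that("free energy is non-increasing over sweeps and convergence is flagged", {
  set.seed(21)
  cases <- list(
    trial_setup("repetition", "L1", "man"),
    trial_setup("naming", "L2", "dog"),
    trial_setup("translation", "L1", "book"))
  for (s in cases) {
    obs <- observation_set(TASK_MODEL)
    obs[, 1] <- environment_step(TASK_MODEL, s, 1L)
    for (p in 1:2) {
      bel <- infer_states(TASK_MODEL, obs, p)
      tr <- bel$iteration_trace
      if (length(tr) > 1)
        expect_true(all(diff(tr) <= 1e-6))
      expect_true(bel$converged)
      for (f in names(TASK_MODEL$factors)) for (tau in 1:2) {
        expect_equal(sum(bel$Q[[f]][, tau]), 1, tolerance = 1e-8)
        expect_true(all(bel$Q[[f]][, tau] >= 0 & bel$Q[[f]][, tau] <= 1))
      }
    }
  }
})

test_that("mean-field marginals track the enumeration oracle on the task model", {
  # single-epoch, single-modality evidence: conditionally independent given
  # the factorisation, so mean-field is near exact
  obs <- observation_set(TASK_MODEL, language = 1L)
  bel <- infer_states(TASK_MODEL, obs, 1L)
  ex <- enumerate_exact_posterior(TASK_MODEL, obs, 1L)
  for (f in names(TASK_MODEL$factors))
    expect_lt(total_variation(bel$Q[[f]][, 1], ex$marginals[[f]][, 1]), 1e-3)

  # full stimulus observation sets from all three tasks
  for (s in list(trial_setup("repetition", "L1", "man"),
                 trial_setup("repetition", "L2", "girl"),
                 trial_setup("naming", "L1", "cat"),
                 trial_setup("translation", "L2", "hat"))) {
    obs <- observation_set(TASK_MODEL)
    obs[, 1] <- environment_step(TASK_MODEL, s, 1L)
    for (p in 1:2) {
      bel <- infer_states(TASK_MODEL, obs, p)
      ex <- enumerate_exact_posterior(TASK_MODEL, obs, p)
      for (f in names(TASK_MODEL$factors)) for (tau in 1:2)
        expect_lt(total_variation(bel$Q[[f]][, tau],
                                  ex$marginals[[f]][, tau]), 0.05)
      # the variational bound: F >= -log evidence
      expect_gte(bel$F, ex$log_evidence * -1 - 1e-8)
    }
  }
})

test_that("expected free energy decomposes into risk plus ambiguity", {
  m <- toy_model(seed = 5, deterministic = TRUE)  # one-hot columns
  obs <- observation_set(m)
  bel <- infer_states(m, obs, 1L)
  efe <- expected_free_energy(m, bel, 1L)
  expect_equal(efe$ambiguity, 0, tolerance = 1e-5)
  expect_equal(efe$G, efe$risk + efe$ambiguity)
  expect_gte(efe$ambiguity, 0)

  # two-state, two-outcome hand case: ambiguity is the expected column
  # entropy, 0.5 * H(0.9, 0.1) + 0.5 * H(0.2, 0.8)
  expect_equal(
    0.5 * .entropy_pub(c(0.9, 0.1)) + 0.5 * .entropy_pub(c(0.2, 0.8)),
    0.4127425, tolerance = 1e-6)

  # uniform preferences: risk = log|O| - entropy of predicted outcomes
  bel2 <- infer_states(TASK_MODEL, observation_set(TASK_MODEL), 1L)
  efe2 <- expected_free_energy(TASK_MODEL, bel2, 1L)
  expect_gte(efe2$risk, 0)
})

test_that("expected free energy matches the brute-force oracle", {
  for (seed in c(2, 9)) {
    m <- toy_model(seed = seed)
    obs <- observation_set(m, x = 1L)
    for (p in 1:2) {
      bel <- infer_states(m, obs, p)
      efe <- expected_free_energy(m, bel, p)
      bf <- efe_bruteforce(m, lapply(bel$Q, function(q) q[, 2]))
      expect_equal(efe$G, bf$G, tolerance = 1e-8)
      expect_equal(efe$risk, bf$risk, tolerance = 1e-8)
      expect_equal(efe$ambiguity, bf$ambiguity, tolerance = 1e-8)
    }
  }
  # and on the full task model
  obs <- observation_set(TASK_MODEL)
  obs[, 1] <- environment_step(TASK_MODEL,
                               trial_setup("repetition", "L1", "man"), 1L)
  bel <- infer_states(TASK_MODEL, obs, 1L)
  efe <- expected_free_energy(TASK_MODEL, bel, 1L)
  bf <- efe_bruteforce(TASK_MODEL, lapply(bel$Q, function(q) q[, 2]))
  expect_equal(efe$G, bf$G, tolerance = 1e-8)
})

test_that("state-risk variant is available and non-negative", {
  obs <- observation_set(TASK_MODEL)
  obs[, 1] <- environment_step(TASK_MODEL,
                               trial_setup("naming", "L1", "man"), 1L)
  bel <- infer_states(TASK_MODEL, obs, 1L)
  efe <- expected_free_energy(TASK_MODEL, bel, 1L, risk_over = "states")
  expect_gte(efe$risk, 0)
  expect_equal(efe$G, efe$risk + efe$ambiguity)
})

test_that("policy posterior is a softmax of -(F + G) with precision gamma", {
  expect_equal(policy_posterior(c(2, 2), c(1, 1)), c(0.5, 0.5))
  p <- policy_posterior(c(0, 0), c(0, 1e6))
  expect_equal(p, c(1, 0), tolerance = 1e-10)
  expect_equal(policy_posterior(c(0, 0), c(1.0, 1.5), gamma = 2),
               c(0.7310586, 0.2689414), tolerance = 1e-6)
  # shift invariance
  expect_equal(policy_posterior(c(1, 2, 3), c(0, 1, 0), gamma = 4),
               policy_posterior(c(11, 12, 13), c(0, 1, 0), gamma = 4))
  expect_equal(sum(policy_posterior(stats::runif(5), stats::runif(5))), 1,
               tolerance = 1e-10)
})

test_that("action selection is argmax with index tie-break, or sampled", {
  pol <- TASK_MODEL$policies
  expect_identical(select_action(c(0.9, 0.1), pol)$policy, 1L)
  expect_identical(select_action(c(0.5, 0.5), pol)$policy, 1L)
  expect_identical(select_action(c(0.1, 0.9), pol)$actions[["target"]], 2L)
  set.seed(123)
  draws <- replicate(1e4,
    select_action(c(0.5, 0.5), pol, mode = "sample")$policy)
  expect_lt(abs(mean(draws == 1L) - 0.5), 0.02)
})
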