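# Generic discrete active-inference machinery: belief updating by variational
# free-energy minimisation, expected free energy, policy posterior and action
# selection. Nothing in this file knows about the language task; the task
# model is supplied as an `aphasim_model`.

#' Softmax function
#'
#' Converts a vector of real values into a probability distribution,
#' `exp(scale * x) / sum(exp(scale * x))`, computed stably by subtracting the
#' maximum first. Order-preserving and invariant to adding a constant to all
#' inputs.
#'
#' @param x numeric vector (finite).
#' @param scale positive inverse-temperature scaling.
#' @return probability vector of the same length.
#' @export
softmax <- function(x, scale = 1) {
  if (length(x) == 0L || !all(is.finite(x)))
    .stopf("softmax requires a non-empty finite vector")
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    .stopf("softmax scale must be a positive scalar")
  z <- exp(scale * (x - max(x)))
  z / sum(z)
}

#' Kullback-Leibler divergence (nats)
#'
#' `KL(q || p) = sum q * log(q / p)`, using the `0 * log(0) = 0` convention
#' for zero entries of `q` and flooring `p` at `floor` inside the logarithm
#' so the divergence is always finite. Non-negative, and zero iff `q == p`.
#'
#' @param q,p probability vectors of equal length.
#' @param floor probability floor for the reference distribution.
#' @return non-negative scalar in nats.
#' @export
kl_divergence <- function(q, p, floor = 1e-8) {
  if (length(q) != length(p))
    .stopf("kl_divergence: length mismatch (%d vs %d)", length(q), length(p))
  if (!.is_prob_vec(q, 1e-6) || !.is_prob_vec(p, 1e-6))
    .stopf("kl_divergence requires probability vectors")
  nz <- q > 0
  sum(q[nz] * (log(q[nz]) - log(pmax(p[nz], floor))))
}

#' Variational free energy of a posterior
#'
#' Free energy is complexity minus accuracy: the divergence of the posterior
#' `q` from the prior, minus the expected log-likelihood of the observed
#' outcome under `q`. It upper-bounds surprise: `F >= -log P(o)`, with
#' equality iff `q` is the exact posterior.
#'
#' @param q posterior over (joint) states.
#' @param prior prior over the same states.
#' @param lik likelihood of the observed outcome under each state,
#'   `P(o | s)` (not necessarily normalised over states).
#' @param floor probability floor.
#' @return scalar free energy in nats.
#' @export
free_energy <- function(q, prior, lik, floor = 1e-8) {
  if (!.is_prob_vec(q, 1e-6) || !.is_prob_vec(prior, 1e-6))
    .stopf("free_energy requires normalised q and prior")
  if (length(lik) != length(q))
    .stopf("free_energy: likelihood length mismatch")
  complexity <- kl_divergence(q, prior, floor)
  nz <- q > 0
  accuracy <- sum(q[nz] * log(pmax(lik[nz], floor)))
  complexity - accuracy
}

# log-likelihood evidence for factor `f` at epoch `tau`: expectation of
# log A over the beliefs about all other factors, for every observed modality.
#' @keywords internal
.likelihood_message <- function(model, obs, Q, f, tau) {
  msg <- rep(0, length(model$factors[[f]]))
  Qs <- lapply(Q, function(q) q[, tau])
  for (m in names(model$modalities)) {
    o <- obs[m, tau]
    if (is.na(o)) next
    lnA_o <- log(.slice_outcome(model$A[[m]], o))
    msg <- msg + .expect_except(lnA_o, Qs, match(f, names(model$factors)))
  }
  msg
}

# Structured variational free energy: each factor's two-epoch chain is a
# joint (pair) belief q_f(s1, s2); factors are independent under q. The pair
# prior is D(s1) * B(s2 | s1, action); evidence enters through the expected
# log-likelihood messages under the product of the other factors' marginals.
#' @keywords internal
.structured_F <- function(model, obs, pairs, Q, actions) {
  Fv <- 0
  for (f in names(model$factors)) {
    q <- pairs[[f]]
    lnp0 <- log(model$D[[f]]) +
      t(log(model$B[[f]][, , actions[[f]]]))  # [s1, s2]
    Fv <- Fv + sum(q * (log(pmax(q, 1e-300)) - lnp0))
  }
  for (tau in seq_len(model$horizon)) {
    Qs <- lapply(Q, function(q) q[, tau])
    w <- .outer_all(Qs)
    for (m in names(model$modalities)) {
      o <- obs[m, tau]
      if (is.na(o)) next
      Fv <- Fv - sum(w * log(.slice_outcome(model$A[[m]], o)))
    }
  }
  Fv
}

#' Infer hidden states under one policy
#'
#' Structured mean-field belief updating for a two-epoch trial: the posterior
#' factorises across hidden-state factors, but within each factor the two
#' epochs' states are kept as a joint (chain) belief, so evidence observed at
#' either epoch is smoothed exactly through that factor's transition. Each
#' sweep updates every factor's chain belief given the expected
#' log-likelihood of the observed outcomes under the other factors' current
#' marginals — an exact coordinate minimisation of the variational free
#' energy, so the free energy recorded after each sweep is non-increasing.
#' Sweeps stop at convergence (max-abs marginal change below `conv_tol`) or
#' after `max_iter` sweeps (returning the best beliefs so far with
#' `converged = FALSE`, never an error).
#'
#' @param model an `aphasim_model` (two-epoch horizon).
#' @param obs an `aphasim_obs` matrix (`NA` for unobserved epochs).
#' @param policy policy index (row of `model$policies`).
#' @param max_iter,conv_tol iteration controls.
#' @return an object of class `aphasim_belief`: list with `Q` (per-factor
#'   level x epoch posterior matrices), `F` (final free energy),
#'   `iteration_trace` (free energy per sweep) and `converged`.
#' @export
infer_states <- function(model, obs, policy = 1L, max_iter = 16L,
                         conv_tol = 1e-4) {
  if (model$horizon != 2L)
    .stopf("infer_states supports two-epoch trials")
  nfac <- names(model$factors)
  actions <- model$policies[policy, ]
  if (ncol(obs) != 2L) .stopf("observation set does not match model horizon")

  lnp0 <- lapply(nfac, function(f)
    log(model$D[[f]]) + t(log(model$B[[f]][, , actions[[f]]])))
  names(lnp0) <- nfac

  Q <- lapply(model$factors, function(lv)
    matrix(1 / length(lv), nrow = length(lv), ncol = 2L,
           dimnames = list(lv, NULL)))
  pairs <- lapply(nfac, function(f) {
    p <- exp(lnp0[[f]])
    p / sum(p)
  })
  names(pairs) <- nfac
  for (f in nfac) {
    Q[[f]][, 1] <- rowSums(pairs[[f]])
    Q[[f]][, 2] <- colSums(pairs[[f]])
  }

  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (f in nfac) {
      m1 <- .likelihood_message(model, obs, Q, f, 1L)
      m2 <- .likelihood_message(model, obs, Q, f, 2L)
      lnq <- lnp0[[f]] + outer(m1, m2, `+`)
      q <- exp(lnq - max(lnq))
      q <- q / sum(q)
      pairs[[f]] <- q
      q1 <- rowSums(q)
      q2 <- colSums(q)
      delta <- max(delta, max(abs(q1 - Q[[f]][, 1])),
                   max(abs(q2 - Q[[f]][, 2])))
      Q[[f]][, 1] <- q1
      Q[[f]][, 2] <- q2
    }
    trace <- c(trace, .structured_F(model, obs, pairs, Q, actions))
    if (delta < conv_tol) {
      converged <- TRUE
      break
    }
  }

  structure(list(Q = Q, pairs = pairs, F = trace[length(trace)],
                 iteration_trace = trace, converged = converged,
                 policy = policy),
            class = "aphasim_belief")
}

#' Expected free energy of a policy
#'
#' For the predictive state beliefs at `future_epoch` under the policy,
#' expected free energy decomposes into risk plus ambiguity. Ambiguity is the
#' expected conditional entropy of outcomes given states, summed over
#' modalities. With the default `risk_over = "outcomes"`, risk is the
#' divergence of the predicted outcome distribution from the preference
#' distribution (softmax of the log-preferences) per modality; with
#' `risk_over = "states"`, it is the divergence of the predicted state
#' beliefs from the prior-predictive state distribution (the initial priors
#' propagated under the policy).
#'
#' @param model an `aphasim_model`.
#' @param belief an `aphasim_belief` from [infer_states()] under the same
#'   policy.
#' @param policy policy index.
#' @param future_epoch epoch whose predicted outcomes are evaluated.
#' @param risk_over `"outcomes"` (default) or `"states"`.
#' @return list with `G`, `risk`, `ambiguity` (all nats).
#' @export
expected_free_energy <- function(model, belief, policy = belief$policy,
                                 future_epoch = model$horizon,
                                 risk_over = c("outcomes", "states")) {
  risk_over <- match.arg(risk_over)
  Qs <- lapply(belief$Q, function(q) q[, future_epoch])
  w <- .outer_all(Qs)

  ambiguity <- 0
  for (m in names(model$modalities)) {
    A <- model$A[[m]]
    flat <- matrix(A, nrow = dim(A)[1])
    colH <- -colSums(flat * log(flat))
    ambiguity <- ambiguity + sum(array(colH, dim = dim(A)[-1]) * w)
  }

  risk <- 0
  if (risk_over == "outcomes") {
    for (m in names(model$modalities)) {
      A <- model$A[[m]]
      Qo <- as.vector(matrix(A, nrow = dim(A)[1]) %*% as.vector(w))
      risk <- risk + kl_divergence(Qo, softmax(model$C[[m]]),
                                   floor = model$floor)
    }
  } else {
    actions <- model$policies[policy, ]
    for (f in names(model$factors)) {
      pf <- model$D[[f]]
      for (tau in seq_len(future_epoch)[-1])
        pf <- as.vector(model$B[[f]][, , actions[[f]]] %*% pf)
      risk <- risk + kl_divergence(Qs[[f]], pf, floor = model$floor)
    }
  }

  list(G = risk + ambiguity, risk = risk, ambiguity = ambiguity)
}

#' Posterior over policies
#'
#' Softmax of `-(F + G)` scaled by the policy precision `gamma`. Invariant to
#' adding a constant to all `F + G` values.
#'
#' @param F,G numeric vectors of variational and expected free energies, one
#'   entry per policy.
#' @param gamma positive policy precision.
#' @return probability vector over policies.
#' @export
policy_posterior <- function(F, G, gamma = 16) {
  if (length(F) != length(G)) .stopf("F and G must have equal length")
  softmax(-(F + G), scale = gamma)
}

#' Select an action from the policy posterior
#'
#' Deterministic mode returns the actions of the maximum-probability policy
#' (ties broken by lowest policy index); sampling mode draws a policy from
#' the posterior using the current random stream.
#'
#' @param post probability vector over policies.
#' @param policies policy matrix (`model$policies`).
#' @param mode `"deterministic"` or `"sample"`.
#' @return list with `policy` (chosen index) and `actions` (named action
#'   index per factor).
#' @export
select_action <- function(post, policies,
                          mode = c("deterministic", "sample")) {
  mode <- match.arg(mode)
  if (!.is_prob_vec(post, 1e-6))
    .stopf("policy posterior must be a probability vector")
  k <- if (mode == "deterministic") which.max(post)
       else sample.int(length(post), 1L, prob = post)
  list(policy = k, actions = policies[k, ])
}
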