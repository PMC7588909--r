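# Exhaustive-enumeration oracles. These compute exact posteriors and expected
# free energies by summing over the full joint state space, independently of
# the mean-field engine, and exist so the engine can be checked against exact
# Bayesian answers on small models (the full task model has 288 joint states).

# Joint-state index bookkeeping: joint states are flattened with factor 1
# varying fastest, matching R's array order and `.outer_all()`.
#' @keywords internal
.joint_size <- function(model) prod(lengths(model$factors))

# Likelihood of the observed outcomes at one epoch as a vector over joint
# states (product over observed modalities).
#' @keywords internal
.joint_likelihood <- function(model, obs, tau) {
  S <- .joint_size(model)
  L <- rep(1, S)
  for (m in names(model$modalities)) {
    o <- obs[m, tau]
    if (is.na(o)) next
    L <- L * as.vector(.slice_outcome(model$A[[m]], o))
  }
  L
}

#' Exact joint posterior by enumeration (test oracle)
#'
#' Sums the full joint distribution over all epochs' hidden states for a fixed
#' action sequence, returning the exact per-factor marginals at every epoch
#' and the exact log evidence. Refuses joint state spaces larger than
#' `max_states`.
#'
#' @param model an `aphasim_model`.
#' @param obs an `aphasim_obs` matrix.
#' @param actions named action index per factor (the single controlled
#'   transition of a one-step policy), or a policy index.
#' @param max_states refusal threshold for the joint state-space size.
#' @return list with `marginals` (per-factor level x epoch matrices),
#'   `joint` (per-epoch exact joint posterior vectors) and `log_evidence`.
#' @export
enumerate_exact_posterior <- function(model, obs, actions = 1L,
                                      max_states = 1e4) {
  if (length(actions) == 1L && is.numeric(actions))
    actions <- model$policies[actions, ]
  S <- .joint_size(model)
  if (S > max_states)
    .stopf("joint state space too large for enumeration (%d > %g)",
           S, max_states)
  Tn <- model$horizon

  # joint transition matrix: kronecker in reverse factor order so that
  # factor 1 varies fastest in the joint index
  Tr <- Reduce(`%x%`, rev(lapply(names(model$factors), function(f)
    model$B[[f]][, , actions[[f]]])))
  p1 <- as.vector(.outer_all(model$D))

  # forward filtering with per-epoch evidence, keeping unnormalised messages
  alpha <- vector("list", Tn)
  alpha[[1]] <- p1 * .joint_likelihood(model, obs, 1L)
  if (Tn > 1) for (tau in 2:Tn)
    alpha[[tau]] <- as.vector(Tr %*% alpha[[tau - 1L]]) *
      .joint_likelihood(model, obs, tau)
  # backward messages
  beta <- vector("list", Tn)
  beta[[Tn]] <- rep(1, S)
  if (Tn > 1) for (tau in (Tn - 1L):1)
    beta[[tau]] <- as.vector(t(Tr) %*%
      (beta[[tau + 1L]] * .joint_likelihood(model, obs, tau + 1L)))

  Z <- sum(alpha[[Tn]])
  joint <- lapply(seq_len(Tn), function(tau)
    alpha[[tau]] * beta[[tau]] / Z)

  dims <- lengths(model$factors)
  marginals <- lapply(seq_along(dims), function(i) {
    out <- vapply(seq_len(Tn), function(tau)
      apply(array(joint[[tau]], dim = dims), i, sum), numeric(dims[[i]]))
    rownames(out) <- model$factors[[i]]
    out
  })
  names(marginals) <- names(model$factors)

  list(marginals = marginals, joint = joint, log_evidence = log(Z))
}

#' Brute-force expected free energy (test oracle)
#'
#' Computes risk and ambiguity by explicit looping over every joint hidden
#' state and every outcome level of every modality, for a given predictive
#' state posterior. Structurally independent of [expected_free_energy()].
#'
#' @param model an `aphasim_model`.
#' @param state_posterior named list of per-factor probability vectors at the
#'   future epoch.
#' @param preferences named list of log-preference vectors (defaults to
#'   `model$C`).
#' @return list with `G`, `risk`, `ambiguity`.
#' @export
efe_bruteforce <- function(model, state_posterior, preferences = model$C) {
  grid <- expand.grid(lapply(lengths(model$factors), seq_len))
  S <- nrow(grid)
  w <- numeric(S)
  for (i in seq_len(S)) {
    p <- 1
    for (f in seq_along(model$factors))
      p <- p * state_posterior[[f]][grid[i, f]]
    w[i] <- p
  }

  risk <- 0
  ambiguity <- 0
  for (m in names(model$modalities)) {
    A <- model$A[[m]]
    K <- dim(A)[1]
    Qo <- numeric(K)
    for (i in seq_len(S)) {
      col <- numeric(K)
      for (o in seq_len(K))
        col[o] <- A[matrix(c(o, as.integer(grid[i, ])), nrow = 1)]
      Qo <- Qo + w[i] * col
      ambiguity <- ambiguity - w[i] * sum(col * log(col))
    }
    cpref <- exp(preferences[[m]] - max(preferences[[m]]))
    cpref <- cpref / sum(cpref)
    risk <- risk + sum(Qo * (log(Qo) - log(cpref)))
  }
  list(G = risk + ambiguity, risk = risk, ambiguity = ambiguity)
}
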