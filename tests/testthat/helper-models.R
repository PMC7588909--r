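# Shared fixtures: the full task model is built once per test run; small toy
# models are generated programmatically.

TASK_MODEL <- build_task_model()
DEFAULT_SCHEDULE <- make_schedule()

# A small random model: three factors (2, 3, 2 levels), two modalities
# (3 and 4 levels), two actions on the first factor. Seeded and normalised.
toy_model <- function(seed = 1, flat_likelihood = FALSE,
                      deterministic = FALSE) {
  set.seed(seed)
  factors <- list(a = c("a1", "a2"), b = c("b1", "b2", "b3"),
                  c = c("c1", "c2"))
  modalities <- list(x = c("x1", "x2", "x3"),
                     y = c("y1", "y2", "y3", "y4"))
  nf <- lengths(factors)
  rand_A <- function(K) {
    arr <- array(stats::runif(K * prod(nf)), dim = c(K, nf))
    if (flat_likelihood) arr[] <- 1
    if (deterministic) {
      flat <- matrix(0, K, prod(nf))
      flat[cbind(sample.int(K, prod(nf), replace = TRUE),
                 seq_len(prod(nf)))] <- 1
      arr <- array(flat, dim = c(K, nf))
    }
    arr
  }
  A <- list(x = rand_A(3L), y = rand_A(4L))
  rand_B <- function(n, n_act = 1L) {
    b <- array(stats::runif(n * n * n_act), dim = c(n, n, n_act))
    if (deterministic) {
      b[] <- 0
      for (u in seq_len(n_act)) b[cbind(sample.int(n, n, TRUE),
                                        seq_len(n), u)] <- 1
    }
    b
  }
  B <- list(a = rand_B(2L, 2L), b = rand_B(3L), c = rand_B(2L))
  D <- lapply(nf, function(n) .norm_unif(n, deterministic))
  C <- list(x = c(0, 1, -1), y = rep(0, 4))
  policies <- matrix(c(1L, 1L, 1L, 2L, 1L, 1L), nrow = 2, byrow = TRUE)
  generative_model(factors, modalities, A, B, D, C, policies)
}

.norm_unif <- function(n, deterministic = FALSE) {
  if (deterministic) {
    d <- rep(0, n)
    d[1] <- 1
    d
  } else {
    x <- stats::runif(n)
    x / sum(x)
  }
}

# Independent, literal-sum oracle used to cross-check the package's
# enumeration oracle: loops over every combination of both epochs' joint
# states with expand.grid, no message passing.
literal_posterior <- function(model, obs, actions = model$policies[1, ]) {
  nf <- lengths(model$factors)
  g1 <- expand.grid(lapply(nf, seq_len))
  S <- nrow(g1)
  lik <- function(row, tau) {
    p <- 1
    for (m in names(model$modalities)) {
      o <- obs[m, tau]
      if (is.na(o)) next
      p <- p * model$A[[m]][matrix(c(o, as.integer(row)), nrow = 1)]
    }
    p
  }
  joint <- matrix(0, S, S)  # [s1, s2]
  for (i in seq_len(S)) {
    p1 <- 1
    for (f in seq_along(nf)) p1 <- p1 * model$D[[f]][g1[i, f]]
    l1 <- lik(g1[i, ], 1L)
    if (p1 * l1 == 0) next
    for (j in seq_len(S)) {
      tr <- 1
      for (f in seq_along(nf))
        tr <- tr * model$B[[f]][g1[j, f], g1[i, f], actions[[f]]]
      joint[i, j] <- p1 * l1 * tr * lik(g1[j, ], 2L)
    }
  }
  Z <- sum(joint)
  list(marg1 = rowSums(joint) / Z, marg2 = colSums(joint) / Z,
       log_evidence = log(Z), grid = g1)
}

# factor marginal from a joint-state vector
factor_marginal <- function(joint_vec, model, f) {
  nf <- lengths(model$factors)
  apply(array(joint_vec, dim = nf), match(f, names(model$factors)), sum)
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

.entropy_pub <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}
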