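#' Construct a discrete generative model
#'
#' A categorical partially observed Markov decision process, factorised into
#' independent hidden-state factors and outcome modalities. Outcomes are
#' generated from the joint hidden state through one likelihood tensor per
#' modality (`A`); states evolve through one action-conditioned transition
#' tensor per factor (`B`); `D` holds initial-state priors and `C` holds
#' log-preferences over outcome levels. Policies assign one action per
#' controllable factor per transition.
#'
#' All probability tensors are floored at `floor` and renormalised on
#' construction, so every stored column is strictly positive and logarithms
#' are finite.
#'
#' @param factors named list; each element a character vector of level names.
#' @param modalities named list; each element a character vector of level
#'   names.
#' @param A named list of likelihood arrays, one per modality, with dimensions
#'   `c(levels(modality), levels(factor 1), ..., levels(factor N))`. Each
#'   column (fixed joint state) must be a distribution over outcome levels.
#' @param B named list of transition arrays, one per factor, with dimensions
#'   `c(levels, levels, actions)`; entry `[s', s, u]` is
#'   `P(next = s' | previous = s, action = u)`. Factors without actions have a
#'   single action slice.
#' @param D named list of initial prior vectors, one per factor.
#' @param C named list of log-preference vectors, one per modality (zeros for
#'   indifferent modalities).
#' @param policies integer matrix with one row per policy and one column per
#'   factor, giving the action index applied to that factor on the single
#'   controlled transition. Row names label the policies.
#' @param horizon number of epochs per trial (default 2: stimulus, then
#'   response plus feedback).
#' @param floor probability floor applied before normalisation.
#'
#' @return An object of class `aphasim_model`.
#' @export
generative_model <- function(factors, modalities, A, B, D, C, policies,
                             horizon = 2L, floor = 1e-8) {
  if (is.null(names(factors)) || is.null(names(modalities)))
    .stopf("factors and modalities must be named lists")
  nf <- lengths(factors)
  nm <- lengths(modalities)

  if (!setequal(names(A), names(modalities)))
    .stopf("A must have one tensor per modality")
  if (!setequal(names(B), names(factors)))
    .stopf("B must have one tensor per factor")
  A <- A[names(modalities)]
  B <- B[names(factors)]
  D <- D[names(factors)]
  C <- C[names(modalities)]

  for (m in names(A)) {
    a <- A[[m]]
    expected <- c(nm[[m]], unname(nf))
    if (!identical(unname(dim(a)), as.integer(expected)))
      .stopf("likelihood '%s' has dimensions (%s), expected (%s)", m,
             paste(dim(a), collapse = ","), paste(expected, collapse = ","))
    flat <- matrix(a, nrow = nm[[m]])
    A[[m]] <- array(.floor_norm_cols(flat, floor), dim = dim(a))
  }
  for (f in names(B)) {
    b <- B[[f]]
    if (length(dim(b)) == 2L) b <- array(b, dim = c(dim(b), 1L))
    if (dim(b)[1] != nf[[f]] || dim(b)[2] != nf[[f]])
      .stopf("transition '%s' is not square in the state dimension", f)
    for (u in seq_len(dim(b)[3])) b[, , u] <- .floor_norm_cols(b[, , u], floor)
    B[[f]] <- b
  }
  for (f in names(D)) {
    if (length(D[[f]]) != nf[[f]])
      .stopf("prior '%s' has wrong length", f)
    D[[f]] <- .floor_norm(D[[f]], floor)
  }
  for (m in names(C)) {
    if (length(C[[m]]) != nm[[m]])
      .stopf("preferences '%s' have wrong length", m)
  }

  policies <- as.matrix(policies)
  if (nrow(policies) < 1L) .stopf("policy set must be non-empty")
  if (ncol(policies) != length(factors))
    .stopf("policies must have one column per factor")
  colnames(policies) <- names(factors)
  for (f in names(factors)) {
    if (any(policies[, f] < 1L | policies[, f] > dim(B[[f]])[3]))
      .stopf("policy indexes an invalid action for factor '%s'", f)
  }

  structure(
    list(factors = factors, modalities = modalities,
         A = A, B = B, D = D, C = C,
         policies = policies, horizon = as.integer(horizon),
         floor = floor),
    class = "aphasim_model")
}

#' @export
print.aphasim_model <- function(x, ...) {
  cat("<aphasim_model>\n")
  cat("  factors:   ",
      paste(sprintf("%s(%d)", names(x$factors), lengths(x$factors)),
            collapse = ", "), "\n")
  cat("  modalities:",
      paste(sprintf("%s(%d)", names(x$modalities), lengths(x$modalities)),
            collapse = ", "), "\n")
  cat("  policies:  ", nrow(x$policies), "one-step policies:",
      paste(rownames(x$policies), collapse = ", "), "\n")
  invisible(x)
}

#' Create an observation set
#'
#' Observed outcome levels per modality per epoch. `NA` marks outcomes not
#' yet observed (future epochs).
#'
#' @param model an `aphasim_model`.
#' @param ... named arguments, one per observed modality, each an integer or
#'   character vector of length `model$horizon` (use `NA` for unobserved
#'   epochs), or a single value observed at epoch 1.
#' @return integer matrix (modalities x epochs) of outcome indices, class
#'   `aphasim_obs`.
#' @export
observation_set <- function(model, ...) {
  given <- list(...)
  obs <- matrix(NA_integer_, nrow = length(model$modalities),
                ncol = model$horizon,
                dimnames = list(names(model$modalities), NULL))
  for (m in names(given)) {
    if (!m %in% names(model$modalities))
      .stopf("unknown modality '%s'", m)
    v <- given[[m]]
    if (is.character(v)) v <- match(v, model$modalities[[m]])
    if (length(v) == 1L) v <- c(v, rep(NA_integer_, model$horizon - 1L))
    if (length(v) != model$horizon)
      .stopf("observations for '%s' must have length 1 or %d", m,
             model$horizon)
    bad <- !is.na(v) & (v < 1L | v > length(model$modalities[[m]]))
    if (any(bad))
      .stopf("invalid outcome level for modality '%s'", m)
    obs[m, ] <- as.integer(v)
  }
  structure(obs, class = c("aphasim_obs", "matrix"))
}

# Slice a likelihood array at one outcome level, returning the array over
# factor dimensions (a function of the joint hidden state).
#' @keywords internal
.slice_outcome <- function(A, o) {
  d <- dim(A)
  idx <- slice.index(array(seq_len(prod(d)), d), 1L)
  array(A[idx == o], dim = d[-1])
}

# Outer product of per-factor vectors, in factor order (factor 1 fastest).
#' @keywords internal
.outer_all <- function(Qs) {
  out <- Reduce(outer, Qs)
  array(out, dim = lengths(Qs))
}

# E over all factors except `keep` of an array defined over factor dims.
#' @keywords internal
.expect_except <- function(arr, Qs, keep) {
  Qs[[keep]] <- rep(1, length(Qs[[keep]]))
  apply(arr * .outer_all(Qs), keep, sum)
}
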