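# Internal numeric helpers shared across the engine and task model.

#' @keywords internal
.norm_vec <- function(x) x / sum(x)

# Floor probabilities at eps and renormalise. Applied to every stored
# distribution before any logarithm is taken, so log() is always finite and
# the omega = 1 lesion is an exact identity on the stored representation.
#' @keywords internal
.floor_norm <- function(x, eps = 1e-8) {
  x <- pmax(x, eps)
  x / sum(x)
}

# Column-wise floor+normalise for a matrix whose columns are distributions.
#' @keywords internal
.floor_norm_cols <- function(m, eps = 1e-8) {
  m <- pmax(m, eps)
  sweep(m, 2, colSums(m), "/")
}

#' @keywords internal
.is_prob_vec <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(x >= -tol) && abs(sum(x) - 1) < tol
}

#' @keywords internal
.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' @keywords internal
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Derive a child seed from a parent seed and an index, staying inside the
# 32-bit integer range R requires of set.seed().
#' @keywords internal
.child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483647L)
}
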