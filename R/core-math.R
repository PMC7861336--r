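# Exact categorical-distribution primitives shared by every other component.
# All log quantities are in nats.

# Additive floor applied before any logarithm so that free-energy quantities
# stay finite for deterministic (zero-entry) distributions.
.log_floor <- exp(-16)

#' Numerically stabilized natural logarithm
#'
#' Adds a fixed floor of `exp(-16)` before taking the log, the standard
#' convention in categorical free-energy schemes.
#'
#' @param x Numeric vector of non-negative values.
#' @return `log(x + exp(-16))`.
#' @keywords internal
log_stable <- function(x) log(x + .log_floor)

#' Softmax (normalized exponential) of a numeric vector
#'
#' @param x Numeric vector (log scale, nats).
#' @return Probability vector proportional to `exp(x)`.
#' @export
#' @examples
#' softmax_vec(c(0, 2, -4))
softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

norm_vec <- function(x) x / sum(x)

one_hot <- function(i, n) {
  v <- numeric(n)
  v[i] <- 1
  v
}

assert_prob <- function(p, tol = 1e-9, arg = deparse(substitute(p))) {
  if (!is.numeric(p) || any(!is.finite(p))) {
    stop(sprintf("'%s' must be a finite numeric vector", arg), call. = FALSE)
  }
  if (any(p < -tol)) {
    stop(sprintf("'%s' has negative entries", arg), call. = FALSE)
  }
  if (abs(sum(p) - 1) > sqrt(tol)) {
    stop(sprintf("'%s' must sum to 1 (got %.12f)", arg, sum(p)), call. = FALSE)
  }
  invisible(p)
}

#' Sharpen a one-hot likelihood by an inverse-temperature softmax
#'
#' Models random-dot-motion coherence: each one-hot column of a likelihood
#' matrix is replaced, within the designated block of ambiguous outcomes (the
#' four cardinal motion directions), by the softmax with inverse temperature
#' `p` of that one-hot vector. The true outcome keeps mass
#' `exp(p) / (exp(p) + K - 1)` for `K` ambiguous outcomes; columns outside the
#' block (the Null state, always observed unambiguously) are left untouched.
#'
#' @param A Matrix whose columns are one-hot distributions over outcomes
#'   (rows), e.g. the noiseless direction-to-observation mapping.
#' @param p Positive inverse temperature (sensory precision). `p -> 0` gives a
#'   uniform distribution over the ambiguous block, `p -> Inf` recovers the
#'   one-hot mapping.
#' @param ambiguous Integer indices of the outcome rows (and the matching
#'   columns) forming the ambiguous block subject to softening. Default `2:5`,
#'   the four motion directions in the task's outcome coding.
#' @return Column-stochastic matrix of the same shape as `A`.
#' @export
#' @examples
#' A <- diag(5)
#' round(sharpen_likelihood(A, p = 5)[, 2], 3) # true direction keeps ~0.98
sharpen_likelihood <- function(A, p, ambiguous = 2:5) {
  if (!is.numeric(p) || length(p) != 1 || !is.finite(p) || p <= 0) {
    stop("'p' must be a single positive precision", call. = FALSE)
  }
  A <- as.matrix(A)
  if (any(A < 0) || any(colSums(A) != 1) || any(A != 0 & A != 1)) {
    stop("'A' must have one-hot columns", call. = FALSE)
  }
  out <- A
  for (j in seq_len(ncol(A))) {
    hot <- which(A[, j] == 1)
    if (!(hot %in% ambiguous) || !(j %in% ambiguous)) next
    block <- numeric(length(ambiguous))
    block[match(hot, ambiguous)] <- p
    out[, j] <- 0
    out[ambiguous, j] <- softmax_vec(block)
  }
  out
}

#' Kullback-Leibler divergence between two categorical distributions
#'
#' Computes `sum(p * log(p / q))` in nats with the `0 * log 0 = 0` convention;
#' entries of `q` are floored at `exp(-16)` to keep the result finite.
#'
#' @param p,q Probability vectors of equal length.
#' @return Non-negative divergence in nats (zero iff `p == q`).
#' @export
#' @examples
#' kl_divergence(c(1, 0), c(0.5, 0.5)) # log(2)
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) {
    stop("'p' and 'q' must have the same length", call. = FALSE)
  }
  assert_prob(p, arg = "p")
  assert_prob(q, arg = "q")
  ii <- p > 0
  sum(p[ii] * (log(p[ii]) - log(pmax(q[ii], .log_floor))))
}

#' Shannon entropy of a categorical distribution
#'
#' @param p Probability vector.
#' @return `-sum(p * log(p))` in nats, with `0 * log 0 = 0`.
#' @export
#' @examples
#' entropy_cat(rep(0.25, 4)) # log(4)
entropy_cat <- function(p) {
  assert_prob(p, arg = "p")
  ii <- p > 0
  -sum(p[ii] * log(p[ii]))
}

# Flatten a likelihood array (outcomes x factor1 [x factor2 ...]) to a matrix
# outcomes x joint-states, joint states in column-major factor order.
flatten_likelihood <- function(A) {
  d <- dim(A)
  if (is.null(d)) stop("'A' must be an array or matrix", call. = FALSE)
  matrix(A, nrow = d[1])
}

#' Per-state outcome entropy (ambiguity) of a likelihood array
#'
#' Entry `j` is the entropy of the outcome distribution conditional on joint
#' hidden state `j` (column-major over the state factors). The dot product of
#' this vector with a predicted state distribution is the ambiguity term of
#' the expected free energy.
#'
#' @param A Likelihood array, dimension (outcomes, states...) with
#'   column-stochastic outcome columns.
#' @return Non-negative numeric vector, one entry per joint hidden state.
#' @export
ambiguity_vector <- function(A) {
  Af <- flatten_likelihood(A)
  cs <- colSums(Af)
  if (any(Af < 0) || any(abs(cs - 1) > 1e-6)) {
    stop("'A' must have column-stochastic outcome distributions", call. = FALSE)
  }
  apply(Af, 2, entropy_cat)
}

# Contract a likelihood array over factor beliefs.
# keep = NULL marginalizes every factor (-> outcome vector);
# keep = f returns the matrix outcomes x states-of-factor-f, contracting the
# remaining factors with their beliefs.
contract_likelihood <- function(A, beliefs, keep = NULL) {
  d <- dim(A)
  nf <- length(d) - 1L
  if (length(beliefs) != nf) {
    stop("number of factor beliefs must match likelihood factors", call. = FALSE)
  }
  for (f in seq_len(nf)) {
    if (length(beliefs[[f]]) != d[f + 1L]) {
      stop("factor belief dimensions do not match likelihood", call. = FALSE)
    }
  }
  perm <- c(1L, setdiff(seq_len(nf), keep) + 1L, if (!is.null(keep)) keep + 1L)
  x <- aperm(A, perm)
  dims <- dim(x)
  for (f in setdiff(seq_len(nf), keep)) {
    # contract the second dimension repeatedly (outcome dim stays first)
    b <- beliefs[[f]]
    x <- array(x, c(dims[1], length(b), prod(dims[-(1:2)])))
    x <- apply(x, c(1, 3), function(v) sum(v * b))
    dims <- dim(x) <- c(dims[1], dims[-(1:2)])
  }
  if (is.null(keep)) as.vector(x) else matrix(x, nrow = d[1])
}

#' Predicted outcome distribution under factorized state beliefs
#'
#' Passes the product of per-factor beliefs through a likelihood array to
#' obtain the outcome marginal ("expected observations").
#'
#' @param A Likelihood array, dimension (outcomes, states of factor 1, ...).
#' @param factor_beliefs List of probability vectors, one per state factor.
#' @return Normalized probability vector over outcomes.
#' @export
predictive_outcomes <- function(A, factor_beliefs) {
  for (b in factor_beliefs) assert_prob(b, arg = "factor_beliefs")
  o <- contract_likelihood(A, factor_beliefs, keep = NULL)
  norm_vec(pmax(o, 0))
}

# Joint distribution over flattened states from per-factor beliefs
# (column-major ordering, matching flatten_likelihood).
joint_belief <- function(beliefs) {
  out <- beliefs[[1]]
  for (f in seq_along(beliefs)[-1]) {
    out <- as.vector(outer(out, beliefs[[f]]))
  }
  out
}
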