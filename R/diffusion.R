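#' Random walk with restart
#'
#' Iterates the propagation recursion
#' \deqn{P_i = (1-\alpha) A_N P_{i-1} + \alpha P_0}
#' to its steady state, where `A_N` is a column-stochastic transition
#' matrix (see [core_transition_matrix()]), `P0` the restart (seed)
#' distribution and `alpha` the restart probability.  The steady-state
#' entries are each node's affinity to the seed set; because the matrix is
#' column-stochastic and the seeds sum to one, total mass is conserved at
#' every step.
#'
#' @param transition Column-stochastic square matrix (dense or sparse).
#' @param seeds Non-negative seed vector summing to 1, aligned to the
#'   matrix columns.
#' @param alpha Restart probability in (0, 1\].  `alpha = 1` returns the
#'   seeds unchanged.
#' @param eps Convergence tolerance on the max-norm change per iteration.
#' @param max_iter Iteration cap; reaching it flags non-convergence
#'   (with a warning) instead of failing.
#' @return A list of class `rwr_scores`: `scores` (named numeric),
#'   `alpha`, `iterations`, `converged`.
#' @seealso [rwr_exact()] for the direct linear solve used as a test
#'   oracle, [quantile_shift()] for the conversion to signed node weights.
#' @export
rwr <- function(transition, seeds, alpha, eps = 1e-10, max_iter = 10000L) {
  if (length(alpha) != 1 || !is.finite(alpha) || alpha <= 0 || alpha > 1) {
    stop_input("`alpha` must be a single value in (0, 1]")
  }
  if (length(eps) != 1 || !is.finite(eps) || eps <= 0) stop_input("`eps` must be > 0")
  n <- nrow(transition)
  if (is.null(n) || n != ncol(transition)) stop_input("transition matrix must be square")
  if (length(seeds) != n) stop_input("seed vector not aligned to the transition matrix")
  cs <- if (inherits(transition, "Matrix")) Matrix::colSums(transition) else colSums(transition)
  if (max(abs(cs - 1)) > 1e-8 || any(transition < 0)) {
    stop_input("transition matrix is not column-stochastic")
  }
  if (any(seeds < 0) || abs(sum(seeds) - 1) > 1e-8) {
    stop_input("seeds must be non-negative and sum to 1")
  }
  p0 <- as.numeric(seeds)
  p <- p0
  it <- 0L
  converged <- (alpha == 1)
  while (!converged && it < max_iter) {
    it <- it + 1L
    p_new <- (1 - alpha) * as.numeric(transition %*% p) + alpha * p0
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta <= eps) {
      converged <- TRUE
    }
  }
  if (!converged) warn(sprintf("RWR did not converge in %d iterations", max_iter))
  nm <- colnames(transition) %||% names(seeds)
  structure(list(scores = setNames(p, nm), alpha = alpha,
                 iterations = it, converged = converged),
            class = "rwr_scores")
}

#' Direct linear solve of the RWR steady state
#'
#' Solves \eqn{P = \alpha (I - (1-\alpha) A_N)^{-1} P_0} exactly.  Meant
#' for validation on small graphs; the power iteration in [rwr()] is the
#' production path.
#'
#' @inheritParams rwr
#' @return Named numeric vector of steady-state scores.
#' @export
rwr_exact <- function(transition, seeds, alpha) {
  n <- nrow(transition)
  M <- diag(n) - (1 - alpha) * as.matrix(transition)
  p <- alpha * solve(M, as.numeric(seeds))
  setNames(as.numeric(p), colnames(transition) %||% names(seeds))
}

#' Quantile shift of propagation scores
#'
#' Subtracts the k-th sample quantile (linear interpolation between order
#' statistics, R's default type 7) from the propagation scores:
#' \deqn{p'_j = p_j - Q_k(P).}
#' For k in (0, 1) on non-constant scores this guarantees both positive
#' and negative node weights, the input the MWCS solver requires; k is
#' approximately the fraction of nodes driven negative, hence acts as the
#' per-iteration filtering rate.
#'
#' @param scores An `rwr_scores` object or a bare numeric vector.
#' @param k Quantile level in \[0, 1\].
#' @return Named numeric vector of shifted weights.
#' @export
quantile_shift <- function(scores, k) {
  if (inherits(scores, "rwr_scores")) scores <- scores$scores
  if (!length(scores)) stop_input("empty score vector")
  assert_scalar_prob(k, "k")
  scores - unname(quantile(scores, probs = k, type = 7))
}

#' @exportS3Method base::print
print.rwr_scores <- function(x, ...) {
  cat(sprintf("<rwr_scores> %d nodes, alpha = %g, %d iterations (%s)\n",
              length(x$scores), x$alpha, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
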