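# Graphical lasso: L1-penalized sparse precision-matrix estimation by block
# coordinate descent over the columns of the covariance estimate W, with a
# coordinate-descent lasso inner loop (off-diagonal penalty only, so the
# diagonal of W stays fixed at diag(S)).

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

glasso_core <- function(S, lambda, tol = 1e-6, max_sweeps = 10000L,
                        B = NULL) {
  p <- ncol(S)
  off <- abs(S[upper.tri(S)])
  mean_off <- if (length(off)) mean(off) else 0
  if (is.null(B)) B <- matrix(0, max(p - 1L, 1L), p)
  if (p == 1L || mean_off == 0) {
    return(list(theta = diag(1 / diag(S), p), W = S, B = B, sweeps = 0L,
                converged = TRUE))
  }
  fit <- glasso_core_cpp(S, lambda, tol, as.integer(max_sweeps), B)
  fit$theta <- (fit$theta + t(fit$theta)) / 2
  fit
}

check_assoc_matrix <- function(S) {
  if (!is.matrix(S) || nrow(S) != ncol(S) ||
      max(abs(S - t(S))) > 1e-8 || any(diag(S) <= 0)) {
    swim_stop("S must be a symmetric association matrix with positive diagonal",
              "swimnet_domain_error")
  }
  invisible(S)
}

#' Graphical lasso fit at a fixed penalty
#'
#' Estimates the sparse precision matrix maximizing the L1-penalized
#' Gaussian log-likelihood
#' `log det(Theta) - tr(S Theta) - lambda * sum_{i != j} |theta_ij|`
#' (off-diagonal penalty only) by block coordinate descent with a lasso
#' inner loop. At `lambda >= max |S_ij|` (i != j) the solution is diagonal;
#' at `lambda = 0` it is the unpenalized maximum-likelihood inverse of `S`.
#'
#' @param S Symmetric association (correlation) matrix.
#' @param lambda Non-negative penalty.
#' @param tol Convergence tolerance as a fraction of the mean absolute
#'   off-diagonal of `S`: a sweep converges when the mean absolute change
#'   of the estimated covariance falls below `tol * mean(|S_offdiag|)`.
#' @param max_sweeps Maximum number of block-coordinate sweeps.
#' @return An object of class `"swim_glasso"`: list with `precision`
#'   (symmetric positive-definite Theta), `lambda`, `converged`,
#'   `iterations`.
#' @export
glasso_fit <- function(S, lambda, tol = 1e-6, max_sweeps = 10000L) {
  check_assoc_matrix(S)
  if (!is.finite(lambda) || lambda < 0) {
    swim_stop("lambda must be a non-negative number", "swimnet_domain_error")
  }
  fit <- glasso_core(S, lambda, tol = tol, max_sweeps = max_sweeps)
  if (!fit$converged) {
    swim_stop(sprintf("graphical lasso did not converge in %d sweeps",
                      fit$sweeps),
              "swimnet_convergence_error", sweeps = fit$sweeps,
              lambda = lambda)
  }
  structure(list(precision = fit$theta, lambda = lambda,
                 converged = fit$converged, iterations = fit$sweeps),
            class = "swim_glasso")
}

#' Penalty path for the graphical lasso
#'
#' Log-spaced decreasing sequence from `lambda_max = max |S_ij|` (the
#' smallest penalty yielding an empty network) down to
#' `lambda_max * min_ratio`.
#'
#' @param S Symmetric association matrix.
#' @param n_lambda Number of penalties (>= 2), default 100.
#' @param min_ratio Ratio of the smallest to the largest penalty,
#'   default 0.01.
#' @return Strictly decreasing numeric vector of penalties.
#' @export
lambda_path <- function(S, n_lambda = 100L, min_ratio = 0.01) {
  check_assoc_matrix(S)
  if (n_lambda < 2L || min_ratio <= 0 || min_ratio >= 1) {
    swim_stop("need n_lambda >= 2 and 0 < min_ratio < 1",
              "swimnet_domain_error")
  }
  lmax <- max(abs(S[upper.tri(S)]))
  if (lmax == 0) {
    swim_stop("all off-diagonal associations are zero: penalty path degenerate",
              "swimnet_degenerate_path")
  }
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' Partial correlations from a precision matrix
#'
#' Standard Gaussian graphical model identity
#' `w_ij = -theta_ij / sqrt(theta_ii * theta_jj)` with zero diagonal: the
#' edge weights of the partial-correlation network.
#'
#' @param theta Symmetric precision matrix with positive diagonal.
#' @return Symmetric weight matrix with zero diagonal, entries in
#'   `[-1, 1]`.
#' @export
precision_to_partial <- function(theta) {
  check_assoc_matrix(theta)
  d <- sqrt(diag(theta))
  w <- -theta / outer(d, d)
  diag(w) <- 0
  (w + t(w)) / 2
}

# Count of nonzero upper-triangle edges of a partial-correlation matrix.
edge_count <- function(w, threshold = 1e-8) {
  sum(abs(w[upper.tri(w)]) > threshold)
}

#' Extended BIC of a Gaussian graphical model
#'
#' `EBIC = -2 l + E log(n) + 4 E gamma log(p)` where
#' `l = (n/2) (log det Theta - tr(S Theta))` (the additive constant
#' `-(np/2) log 2 pi` is omitted: it cancels across models fitted to the
#' same data) and `E` is the number of nonzero upper-triangle edges
#' (partial correlations above `1e-8` in magnitude). `gamma = 0` recovers
#' the ordinary BIC; larger `gamma` favours sparser models.
#'
#' @param theta Symmetric positive-definite precision matrix.
#' @param S Sample association matrix.
#' @param n Sample size.
#' @param gamma EBIC hyperparameter, typically in `[0, 0.5]`.
#' @return The EBIC value (smaller is better).
#' @export
ebic_score <- function(theta, S, n, gamma = 0.25) {
  check_assoc_matrix(S)
  ch <- tryCatch(chol(theta), error = function(e) NULL)
  if (is.null(ch)) {
    swim_stop("theta must be positive-definite", "swimnet_domain_error")
  }
  p <- ncol(theta)
  logdet <- 2 * sum(log(diag(ch)))
  ll <- (n / 2) * (logdet - sum(S * theta))
  E <- edge_count(precision_to_partial(theta))
  -2 * ll + E * log(n) + 4 * E * gamma * log(p)
}

# Maximum KKT residual of the penalized objective at theta (diagnostic).
glasso_kkt <- function(theta, S, lambda) {
  G <- solve(theta) - S
  diag_res <- max(abs(diag(G)))
  off <- row(G) != col(G)
  active <- off & abs(theta) > 1e-10
  inact <- off & !active
  res <- diag_res
  if (any(active)) {
    res <- max(res, max(abs(G[active] - lambda * sign(theta[active]))))
  }
  if (any(inact)) res <- max(res, max(pmax(abs(G[inact]) - lambda, 0)))
  res
}
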