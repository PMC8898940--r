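#' Pearson association matrix of a change matrix
#'
#' Input standardization for the partial-correlation network: the Pearson
#' product-moment correlation matrix of all columns, including a 1/2-coded
#' dichotomous gender column treated numerically.
#'
#' @param x Numeric matrix or data frame, n >= 3 rows, no missing values,
#'   every column with positive variance.
#' @return p-by-p correlation matrix with unit diagonal.
#' @export
cor_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x)) {
    swim_stop("x must be a numeric matrix without missing values",
              "swimnet_domain_error")
  }
  if (nrow(x) < 3L) {
    swim_stop("need at least 3 observations for a correlation matrix",
              "swimnet_insufficient_sample")
  }
  v <- apply(x, 2, sd)
  if (any(v == 0)) {
    bad <- colnames(x)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    swim_stop(sprintf("zero-variance column(s): %s",
                      paste(bad, collapse = ", ")),
              "swimnet_degenerate_column")
  }
  cor(x)
}

#' Fit a regularized partial-correlation network
#'
#' The central model of the package: a pairwise Markov random field
#' (Gaussian graphical model) over the columns of `x`, estimated by the
#' graphical lasso along a decreasing penalty path and selected by the
#' extended Bayesian information criterion. The selected precision matrix
#' is reported as partial correlations
#' `w_ij = -theta_ij / sqrt(theta_ii theta_jj)`; penalized estimates are
#' reported without refitting, following the convention of the network
#' psychometrics software this estimator mirrors.
#'
#' `gamma` controls how strongly the EBIC prefers sparse models: 0 is the
#' ordinary BIC, 0.5 very conservative; 0.25 is the usual exploratory
#' default. EBIC ties are broken toward the larger penalty (sparser
#' model). Fitting with fewer observations than nodes is permitted -- the
#' regularization is what makes that feasible -- but triggers a stability
#' warning.
#'
#' @param x Observation matrix (rows = swimmers, columns = gender plus
#'   percent-change variables), e.g. from [change_matrix()], or any
#'   numeric matrix/data frame.
#' @param gamma EBIC hyperparameter, default 0.25.
#' @param n_lambda Length of the penalty path, default 100.
#' @param lambda_min_ratio Smallest/largest penalty ratio, default 0.01.
#' @param groups Optional integer vector of node groups (defaults to
#'   `attr(x, "groups")` when present).
#' @param tol,max_sweeps Convergence control passed to [glasso_fit()].
#' @param threshold Absolute partial correlations at or below this value
#'   are treated as absent edges (default 1e-8).
#' @return An object of class `"pcnetwork"` with components `weights`
#'   (partial-correlation matrix), `precision`, `lambda` (selected
#'   penalty), `gamma`, `ebic`, `trace` (data frame with one row per
#'   penalty: `lambda`, `edges`, `loglik`, `ebic`), `nodes` (data frame
#'   `name`, `group`), `S`, `n`, `p`, `call`.
#' @seealso [centrality_table()], [lambda_path()], [ebic_score()]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 100, 3) %*% chol(matrix(c(1, .5, .3,
#'                                                   .5, 1, .1,
#'                                                   .3, .1, 1), 3))
#' fit <- pcnetwork(x, gamma = 0.25)
#' coef(fit)
#' @export
pcnetwork <- function(x, gamma = 0.25, n_lambda = 100L,
                      lambda_min_ratio = 0.01,
                      groups = attr(x, "groups"),
                      tol = 1e-6, max_sweeps = 10000L, threshold = 1e-8) {
  cl <- match.call()
  if (!is.finite(gamma) || gamma < 0) {
    swim_stop("gamma must be non-negative", "swimnet_domain_error")
  }
  xm <- as.matrix(x)
  S <- cor_matrix(xm)
  n <- nrow(xm)
  p <- ncol(S)
  if (n < p) {
    warning(sprintf(paste("fewer observations (%d) than nodes (%d):",
                          "the selected network may be unstable"), n, p),
            call. = FALSE)
  }
  path <- lambda_path(S, n_lambda = n_lambda, min_ratio = lambda_min_ratio)
  trace <- data.frame(lambda = path, edges = NA_integer_,
                      loglik = NA_real_, ebic = NA_real_)
  fits <- vector("list", length(path))
  B <- NULL
  for (k in seq_along(path)) {
    fit <- glasso_core(S, path[k], tol = tol, max_sweeps = max_sweeps, B = B)
    if (!fit$converged) {
      swim_stop(sprintf("graphical lasso did not converge at lambda = %.4g",
                        path[k]),
                "swimnet_convergence_error", trace = trace)
    }
    B <- fit$B
    theta <- fit$theta
    ch <- chol(theta)
    ll <- (n / 2) * (2 * sum(log(diag(ch))) - sum(S * theta))
    w <- precision_to_partial(theta)
    E <- edge_count(w, threshold)
    trace$edges[k] <- E
    trace$loglik[k] <- ll
    trace$ebic[k] <- -2 * ll + E * log(n) + 4 * E * gamma * log(p)
    fits[[k]] <- list(theta = theta, w = w)
  }
  best <- which.min(trace$ebic) # first minimum = largest lambda on ties
  w <- fits[[best]]$w
  w[abs(w) <= threshold] <- 0
  node_names <- colnames(S)
  if (is.null(node_names)) node_names <- paste0("V", seq_len(p))
  if (is.null(groups)) groups <- rep(1L, p)
  dimnames(w) <- dimnames(fits[[best]]$theta) <- list(node_names, node_names)
  structure(list(
    weights = w,
    precision = fits[[best]]$theta,
    lambda = path[best],
    gamma = gamma,
    ebic = trace$ebic[best],
    trace = trace,
    nodes = data.frame(name = node_names, group = groups,
                       stringsAsFactors = FALSE),
    S = S, n = n, p = p,
    technique = attr(x, "technique"),
    threshold = threshold,
    call = cl
  ), class = "pcnetwork")
}

#' @export
print.pcnetwork <- function(x, ...) {
  cat("Partial-correlation network (graphical lasso, EBIC-selected)\n")
  if (!is.null(x$technique)) {
    cat(sprintf("  technique: %s\n", toupper(x$technique)))
  }
  cat(sprintf("  nodes: %d   observations: %d\n", x$p, x$n))
  cat(sprintf("  gamma: %.2f   selected lambda: %.4g   EBIC: %.2f\n",
              x$gamma, x$lambda, x$ebic))
  cat(sprintf("  edges: %d of %d possible\n",
              edge_count(x$weights, x$threshold), x$p * (x$p - 1) / 2))
  invisible(x)
}

#' @export
summary.pcnetwork <- function(object, n_edges = 6L, ...) {
  w <- object$weights
  ut <- which(upper.tri(w) & abs(w) > object$threshold, arr.ind = TRUE)
  edges <- data.frame(
    node_a = rownames(w)[ut[, 1]],
    node_b = colnames(w)[ut[, 2]],
    weight = w[ut],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(-abs(edges$weight)), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(fit = object, edges = edges, n_edges = n_edges),
            class = "summary.pcnetwork")
}

#' @export
print.summary.pcnetwork <- function(x, ...) {
  print(x$fit)
  k <- min(x$n_edges, nrow(x$edges))
  if (k > 0) {
    cat(sprintf("\nStrongest %d edges (partial correlations):\n", k))
    print(format(x$edges[seq_len(k), ], digits = 2), row.names = FALSE)
  } else {
    cat("\nEmpty network: no edges selected.\n")
  }
  invisible(x)
}

#' @export
coef.pcnetwork <- function(object, ...) object$weights

#' Draw samples from a fitted partial-correlation network
#'
#' Simulates multivariate-normal observations (on the correlation scale of
#' the fitted data) from the inverse of the selected precision matrix.
#'
#' @param object A [pcnetwork()] fit.
#' @param nsim Number of rows to draw (default: the fitted sample size).
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return `nsim` x p numeric matrix with the network's node names.
#' @export
simulate.pcnetwork <- function(object, nsim = object$n, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- solve(object$precision)
  sigma <- (sigma + t(sigma)) / 2
  x <- MASS::mvrnorm(nsim, mu = rep(0, object$p), Sigma = sigma)
  colnames(x) <- object$nodes$name
  x
}

#' Plot a partial-correlation network
#'
#' Draws the network with the usual psychometric-network colour
#' convention: green edges for positive partial correlations, red for
#' negative, width proportional to magnitude; vertices coloured by node
#' group.
#'
#' @param x A [pcnetwork()] fit.
#' @param ... Passed on to [igraph::plot.igraph()].
#' @export
plot.pcnetwork <- function(x, ...) {
  g <- weight_graph(x$weights, threshold = x$threshold)
  ew <- igraph::E(g)$weight_signed
  igraph::V(g)$color <- c("lightblue", "lightgreen", "gold")[
    ((x$nodes$group - 1L) %% 3L) + 1L]
  igraph::plot.igraph(
    g,
    edge.color = ifelse(ew > 0, "darkgreen", "red"),
    edge.width = 1 + 6 * abs(ew),
    layout = igraph::layout_in_circle(g),
    ...
  )
  invisible(x)
}
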