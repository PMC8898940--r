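# Independent oracles used by the tests. These deliberately share no code
# with the package: the glasso oracle is a proximal-gradient (ISTA) solver
# of the penalized likelihood, the centrality oracles enumerate all simple
# paths, and the small statistical oracles are direct transcriptions of
# the defining formulas.

# ---- graphical lasso: proximal-gradient solver of
#      max log det(Theta) - tr(S Theta) - lambda * sum_{i!=j} |theta_ij|

oracle_penalized_objective <- function(theta, S, lambda) {
  ch <- tryCatch(chol(theta), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  off <- theta
  diag(off) <- 0
  2 * sum(log(diag(ch))) - sum(S * theta) - lambda * sum(abs(off))
}

oracle_kkt <- function(theta, S, lambda) {
  G <- solve(theta) - S
  res <- max(abs(diag(G)))
  off <- row(G) != col(G)
  act <- off & abs(theta) > 1e-10
  ina <- off & !act
  if (any(act)) res <- max(res, max(abs(G[act] - lambda * sign(theta[act]))))
  if (any(ina)) res <- max(res, max(pmax(abs(G[ina]) - lambda, 0)))
  res
}

oracle_glasso <- function(S, lambda, kkt_tol = 1e-7, max_iter = 200000L) {
  p <- ncol(S)
  theta <- diag(1 / diag(S), p)
  f <- oracle_penalized_objective(theta, S, lambda)
  step <- 0.1
  for (it in seq_len(max_iter)) {
    G <- solve(theta) - S
    repeat {
      cand <- theta + step * G
      off <- cand
      diag(off) <- 0
      off <- sign(off) * pmax(abs(off) - step * lambda, 0)
      diag(off) <- diag(cand)
      cand <- (off + t(off)) / 2
      fc <- oracle_penalized_objective(cand, S, lambda)
      if (is.finite(fc) && fc >= f - 1e-14) break
      step <- step / 2
      if (step < 1e-14) return(theta)
    }
    theta <- cand
    f <- fc
    step <- min(step * 1.2, 1)
    if (it %% 25 == 0 && oracle_kkt(theta, S, lambda) < kkt_tol) break
  }
  theta
}

random_correlation <- function(p, n = 40, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cor(matrix(rnorm(n * p), n, p))
}

# ---- centrality: exhaustive enumeration over simple paths

oracle_all_paths <- function(len, s, t) {
  p <- nrow(len)
  out <- list()
  rec <- function(node, visited, total) {
    if (node == t) {
      out[[length(out) + 1L]] <<- list(len = total, nodes = visited)
      return(invisible())
    }
    for (nb in seq_len(p)) {
      if (is.finite(len[node, nb]) && !(nb %in% visited)) {
        rec(nb, c(visited, nb), total + len[node, nb])
      }
    }
  }
  rec(s, s, 0)
  out
}

oracle_centrality <- function(W, threshold = 1e-8) {
  p <- nrow(W)
  len <- 1 / abs(W)
  len[abs(W) <= threshold] <- Inf
  diag(len) <- Inf
  D <- matrix(Inf, p, p)
  diag(D) <- 0
  bet <- numeric(p)
  for (s in seq_len(p - 1)) {
    for (t in (s + 1):p) {
      paths <- oracle_all_paths(len, s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, `[[`, 0, "len")
      dmin <- min(lens)
      D[s, t] <- D[t, s] <- dmin
      short <- paths[lens <= dmin * (1 + 1e-10)]
      for (i in setdiff(seq_len(p), c(s, t))) {
        through <- sum(vapply(short, function(pp) i %in% pp$nodes,
                              logical(1)))
        bet[i] <- bet[i] + through / length(short)
      }
    }
  }
  clo <- vapply(seq_len(p), function(i) {
    d <- D[i, -i]
    if (length(d) == 0 || any(!is.finite(d))) 0 else 1 / sum(d)
  }, numeric(1))
  list(betweenness = bet, closeness = clo,
       strength = rowSums(abs(W) * (abs(W) > threshold)))
}

random_weight_matrix <- function(p, edge_prob = 0.5) {
  W <- matrix(0, p, p)
  for (j in seq_len(p - 1)) {
    for (i in (j + 1):p) {
      if (runif(1) < edge_prob) {
        W[i, j] <- W[j, i] <- runif(1, 0.2, 0.9) * sample(c(-1, 1), 1)
      }
    }
  }
  W
}

# ---- maturity offset: independent term-by-term transcription

oracle_maturity_offset <- function(sex, age, height, sitting_height,
                                   body_mass) {
  ll <- height - sitting_height
  ratio100 <- 100 * body_mass / height
  if (sex == "M") {
    t1 <- 0.0002708 * (ll * sitting_height)
    t2 <- 0.001663 * (age * ll)
    t3 <- 0.007216 * (age * sitting_height)
    t4 <- 0.02292 * ratio100
    -9.236 + t1 - t2 + t3 + t4
  } else {
    t1 <- 0.0001882 * (ll * sitting_height)
    t2 <- 0.0022 * (age * ll)
    t3 <- 0.005847 * (age * sitting_height)
    t4 <- 0.002658 * (age * body_mass)
    t5 <- 0.07693 * ratio100
    -9.376 + t1 + t2 + t3 - t4 + t5
  }
}

# ---- two-pass covariance/correlation oracle

oracle_correlation <- function(x) {
  n <- nrow(x)
  p <- ncol(x)
  mu <- colSums(x) / n
  cv <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      cv[i, j] <- sum((x[, i] - mu[i]) * (x[, j] - mu[j])) / (n - 1)
    }
  }
  d <- sqrt(diag(cv))
  cv / outer(d, d)
}

# ---- shared fixture: a small deterministic valid cohort

tiny_cohort <- function(n_girls = 4, n_boys = 4, seed = 101) {
  simulate_cohort(cohort_config(n_girls = n_girls, n_boys = n_boys,
                                seed = seed))$cohort
}
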