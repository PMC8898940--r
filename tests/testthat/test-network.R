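test_that("the association matrix is the Pearson correlation", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  S <- cor_matrix(x)
  expect_equal(S["a", "b"], 1)
  expect_equal(S["a", "c"], -1)
  set.seed(8)
  y <- matrix(rnorm(100 * 5), 100, 5)
  expect_equal(cor_matrix(y), oracle_correlation(y), tolerance = 1e-12,
               ignore_attr = TRUE)
  bad <- cbind(a = rnorm(10), flat = rep(2, 10))
  err <- tryCatch(cor_matrix(bad), error = identity)
  expect_s3_class(err, "swimnet_degenerate_column")
  expect_match(conditionMessage(err), "flat")
})

test_that("glasso endpoints: empty at lambda_max, inverse at lambda zero", {
  set.seed(13)
  x <- matrix(rnorm(100 * 4), 100, 4)
  S <- cor(x)
  lmax <- max(abs(S[upper.tri(S)]))
  empty <- glasso_fit(S, lmax)
  off <- empty$precision
  diag(off) <- 0
  expect_lt(max(abs(off)), 1e-8)
  expect_equal(diag(empty$precision), 1 / diag(S))
  full <- glasso_fit(S, 0, tol = 1e-9)
  expect_lt(max(abs(full$precision - solve(S))), 1e-6)
})

test_that("glasso solves the penalized likelihood (fixed 3x3 instance)", {
  S <- matrix(c(1, 0.5, 0.3,
                0.5, 1, 0.1,
                0.3, 0.1, 1), 3, 3)
  fit <- glasso_fit(S, 0.2)
  expect_lt(max(abs(fit$precision - t(fit$precision))), 1e-8)
  expect_lt(swimnet:::glasso_kkt(fit$precision, S, 0.2), 1e-5)
  ref <- oracle_glasso(S, 0.2)
  expect_lt(max(abs(fit$precision - ref)), 1e-5)
})

test_that("glasso matches the proximal-gradient oracle on random instances", {
  set.seed(77)
  for (i in 1:10) {
    p <- sample(2:6, 1)
    S <- random_correlation(p)
    lambda <- runif(1, 0.05, 0.9) * max(abs(S[upper.tri(S)]))
    fit <- glasso_fit(S, lambda)
    ref <- oracle_glasso(S, lambda)
    expect_lt(max(abs(fit$precision - ref)), 1e-4)
  }
})

test_that("the penalty path is log-spaced and decreasing", {
  S <- diag(2)
  S[1, 2] <- S[2, 1] <- 0.8
  expect_equal(lambda_path(S, 3, 0.01), c(0.8, 0.08, 0.008))
  path <- lambda_path(S, 50, 0.05)
  expect_equal(length(path), 50)
  expect_true(all(diff(path) < 0))
  expect_equal(path[1], 0.8)
  expect_equal(path[50], 0.8 * 0.05)
  expect_error(lambda_path(diag(3)), class = "swimnet_degenerate_path")
  expect_error(lambda_path(S, 1), class = "swimnet_domain_error")
})

test_that("partial correlations derive from the precision matrix", {
  expect_equal(precision_to_partial(diag(4)), matrix(0, 4, 4))
  theta <- matrix(c(2, -1, -1, 2), 2, 2)
  expect_equal(precision_to_partial(theta)[1, 2], 0.5)
  set.seed(30)
  A <- crossprod(matrix(rnorm(36), 6, 6)) + diag(6)
  w <- precision_to_partial(A)
  expect_equal(w, t(w))
  expect_equal(diag(w), rep(0, 6))
  expect_true(all(abs(w) <= 1 + 1e-12))
  expect_error(precision_to_partial(matrix(c(0, 1, 1, 1), 2)),
               class = "swimnet_domain_error")
})

test_that("the EBIC matches term-by-term arithmetic and reduces to BIC", {
  theta <- matrix(c(1.2, -0.3, 0,
                    -0.3, 1.1, 0.2,
                    0, 0.2, 1.3), 3, 3)
  S <- matrix(c(1, 0.4, 0.2,
                0.4, 1, -0.1,
                0.2, -0.1, 1), 3, 3)
  n <- 20
  ll <- (n / 2) * (determinant(theta)$modulus[1] - sum(diag(S %*% theta)))
  E <- 2 # two nonzero off-diagonal pairs
  expect_equal(ebic_score(theta, S, n, 0.25),
               -2 * ll + E * log(n) + 4 * E * 0.25 * log(3),
               tolerance = 1e-12)
  expect_equal(ebic_score(theta, S, n, 0), -2 * ll + E * log(n),
               tolerance = 1e-12)
  # an empty model's EBIC is the bare deviance
  d <- diag(c(1.5, 2, 0.5))
  lld <- (n / 2) * (determinant(d)$modulus[1] - sum(diag(S %*% d)))
  expect_equal(ebic_score(d, S, n, 0.25), -2 * lld, tolerance = 1e-12)
  expect_error(ebic_score(matrix(c(1, 2, 2, 1), 2), diag(2), 10),
               class = "swimnet_domain_error")
})

test_that("network selection recovers a chain and respects gamma", {
  p <- 6
  theta <- diag(p)
  for (i in 1:(p - 1)) theta[i, i + 1] <- theta[i + 1, i] <- -0.35
  set.seed(99)
  x <- MASS::mvrnorm(1000, rep(0, p), solve(theta))
  fit <- pcnetwork(x, gamma = 0.25)
  est <- abs(coef(fit)) > 1e-8
  want <- abs(theta) > 1e-8
  diag(want) <- FALSE
  # every chain edge is recovered; scoring penalized (non-refit) estimates
  # admits a few weak extra edges, but the model stays well short of
  # saturated (an independent solver selects this same edge set)
  expect_true(all(est[want]))
  expect_lt(sum(est[upper.tri(est)]), p * (p - 1) / 2)
  # the recovered chain edges dominate the extras in magnitude
  expect_gt(min(abs(coef(fit))[want]), max(abs(coef(fit))[!want & !diag(p)]))
  # near-independent data yield an empty network
  set.seed(100)
  x0 <- matrix(rnorm(1000 * 5), 1000, 5)
  fit0 <- pcnetwork(x0)
  expect_equal(sum(abs(coef(fit0))), 0)
  # larger gamma is never denser
  e_sparse <- sum(abs(coef(pcnetwork(x, gamma = 0.5))) > 1e-8)
  e_dense <- sum(abs(coef(pcnetwork(x, gamma = 0))) > 1e-8)
  expect_lte(e_sparse, e_dense)
})

test_that("the selected network is scale invariant and carries its trace", {
  set.seed(55)
  gg <- sample_ggm(p = 6, edge_density = 0.3, pcor_range = c(0.3, 0.4),
                   n = 150, seed = 4)
  fit <- pcnetwork(gg$data)
  scaled <- gg$data
  scaled[, 2] <- scaled[, 2] * 1000
  scaled[, 5] <- scaled[, 5] * 0.004
  fit2 <- pcnetwork(scaled)
  expect_lt(max(abs(coef(fit) - coef(fit2))), 1e-8)
  expect_equal(fit$lambda, fit2$lambda)
  # trace invariants: decreasing path, edge counts within range, selected
  # row is the EBIC minimum
  expect_true(all(diff(fit$trace$lambda) < 0))
  expect_true(all(fit$trace$edges >= 0 & fit$trace$edges <= 15))
  expect_equal(fit$trace$edges[1], 0)
  expect_equal(fit$ebic, min(fit$trace$ebic))
  expect_equal(fit$lambda, fit$trace$lambda[which.min(fit$trace$ebic)])
})

test_that("few observations trigger a stability warning, not an error", {
  set.seed(60)
  x <- matrix(rnorm(8 * 10), 8, 10)
  expect_warning(fit <- pcnetwork(x, n_lambda = 20), "fewer observations")
  expect_s3_class(fit, "pcnetwork")
})

test_that("pcnetwork methods expose the fit", {
  set.seed(61)
  gg <- sample_ggm(p = 5, edge_density = 0.4, pcor_range = c(0.3, 0.45),
                   n = 200, seed = 6)
  fit <- pcnetwork(gg$data)
  expect_output(print(fit), "Partial-correlation network")
  expect_output(print(summary(fit)), "edges")
  expect_identical(coef(fit), fit$weights)
  sim <- simulate(fit, nsim = 50, seed = 1)
  expect_equal(dim(sim), c(50, 5))
  sim2 <- simulate(fit, nsim = 50, seed = 1)
  expect_identical(sim, sim2)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
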