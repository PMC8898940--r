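test_that("sample_ggm realizes the requested structure exactly", {
  gg <- sample_ggm(p = 8, edge_density = 0.25, pcor_range = c(0.3, 0.4),
                   n = 50, seed = 2)
  pc <- gg$truth$pcor
  off <- abs(pc[upper.tri(pc)])
  present <- off[off > 1e-12]
  expect_equal(length(present), round(0.25 * 28))
  expect_true(all(present >= 0.3 & present <= 0.4))
  ev <- eigen(gg$truth$theta, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_equal(dim(gg$data), c(50, 8))
  # determinism
  gg2 <- sample_ggm(p = 8, edge_density = 0.25, pcor_range = c(0.3, 0.4),
                    n = 50, seed = 2)
  expect_identical(gg, gg2)
})

test_that("zero density gives independent columns", {
  gg <- sample_ggm(p = 5, edge_density = 0, n = 2000, seed = 3)
  expect_equal(gg$truth$theta, diag(5))
  S <- cor(gg$data)
  expect_lt(max(abs(S[upper.tri(S)])), 0.1)
})

test_that("a single p = 2 edge reproduces its correlation at large n", {
  # for two variables the partial correlation is the correlation
  gg <- sample_ggm(p = 2, edge_density = 1, pcor_range = c(0.5, 0.5),
                   n = 1e5, seed = 4)
  expect_equal(abs(gg$truth$pcor[1, 2]), 0.5)
  expect_equal(abs(cor(gg$data)[1, 2]), 0.5, tolerance = 0.01)
})

test_that("invalid generator configurations error", {
  expect_error(sample_ggm(p = 1, edge_density = 0.5, n = 10, seed = 1),
               class = "swimnet_config_error")
  expect_error(sample_ggm(p = 4, edge_density = 2, n = 10, seed = 1),
               class = "swimnet_config_error")
  expect_error(sample_ggm(p = 4, edge_density = 0.5,
                          pcor_range = c(0.5, 1.5), n = 10, seed = 1),
               class = "swimnet_config_error")
})

test_that("simulated cohorts satisfy every measurement invariant", {
  sim <- simulate_cohort(cohort_config(n_girls = 30, n_boys = 30, seed = 12))
  x <- sim$cohort
  expect_equal(nrow(x), 120)
  expect_equal(nrow(validate_cohort(x)), 0)
  expect_true(all(x$sitting_height_cm < x$height_cm))
  expect_true(all(x$breast_t10_s < x$breast_t25_s))
  expect_true(all(x$fly_t10_s < x$fly_t25_s))
  num <- x[, !(names(x) %in% c("swimmer_id", "session", "sex"))]
  expect_true(all(unlist(num) > 0))
  # determinism: identical seed, identical cohort
  sim2 <- simulate_cohort(cohort_config(n_girls = 30, n_boys = 30,
                                        seed = 12))
  expect_identical(sim$cohort, sim2$cohort)
})

test_that("percent-change calibration hits the configured targets", {
  cfg <- cohort_config(n_girls = 100, n_boys = 100, seed = 31)
  sim <- simulate_cohort(cfg)
  ps <- swimnet:::pair_sessions(sim$cohort)
  # directly generated variables land exactly on their targets
  d_height <- percent_change(ps$before$height_cm, ps$after$height_cm)
  expect_equal(mean(d_height), cfg$change$height[["mean"]], tolerance = 1e-9)
  expect_equal(sd(d_height), cfg$change$height[["sd"]], tolerance = 1e-9)
  v_b <- 10 / ps$before$breast_t10_s
  v_a <- 10 / ps$after$breast_t10_s
  d_v <- percent_change(v_b, v_a)
  expect_equal(mean(d_v), cfg$change$v_breast[["mean"]], tolerance = 1e-9)
  expect_equal(sd(d_v), cfg$change$v_breast[["sd"]], tolerance = 1e-9)
})

test_that("zero loadings decouple the change scores", {
  cfg <- cohort_config(n_girls = 100, n_boys = 100, seed = 77,
                       loadings = c(age = 0, height = 0, arm_span = 0,
                                    body_mass = 0, v_breast = 0,
                                    sr_breast = 0, v_fly = 0, sr_fly = 0))
  sim <- simulate_cohort(cfg)
  ps <- swimnet:::pair_sessions(sim$cohort)
  d <- cbind(
    percent_change(ps$before$height_cm, ps$after$height_cm),
    percent_change(ps$before$arm_span_cm, ps$after$arm_span_cm),
    percent_change(ps$before$body_mass_kg, ps$after$body_mass_kg),
    percent_change(10 / ps$before$breast_t10_s, 10 / ps$after$breast_t10_s)
  )
  r <- cor(d)
  expect_lt(max(abs(r[upper.tri(r)])), 0.15)
})

test_that("empty or degenerate cohort configurations error", {
  expect_error(simulate_cohort(cohort_config(n_girls = 0, n_boys = 0)),
               class = "swimnet_config_error")
  expect_error(cohort_config(loadings = c(age = 2)),
               class = "swimnet_config_error")
  expect_error(cohort_config(nonsense = 1), class = "swimnet_config_error")
})

test_that("strong latent coupling surfaces as kinematic strength centrality", {
  # with the factor loaded almost entirely on the kinematic changes, the
  # kinematic nodes should dominate strength in most replicates
  hits <- 0L
  for (seed in 1:10) {
    cfg <- cohort_config(
      n_girls = 30, n_boys = 30, seed = seed,
      loadings = c(age = 0.1, height = 0.2, arm_span = 0.2,
                   body_mass = 0.2, v_breast = 0.9, sr_breast = 0.9,
                   v_fly = 0.9, sr_fly = 0.9))
    sim <- simulate_cohort(cfg)
    x <- change_matrix(sim$cohort, "breast")
    fit <- pcnetwork(x, n_lambda = 40)
    ct <- centrality_table(fit)
    top <- ct$node[which.max(ct$strength_z)]
    if (top %in% c("d_v", "d_sr", "d_sl", "d_si", "d_t25")) hits <- hits + 1L
  }
  expect_gte(hits, 6)
})
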