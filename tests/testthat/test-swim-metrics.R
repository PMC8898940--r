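test_that("speed and stroke rate follow their defining ratios", {
  expect_equal(swim_speed(10, 12.5), 0.8)
  expect_equal(swim_speed(10, 10), 1.0)
  sr <- stroke_rate(3, 4)
  expect_equal(sr$cps, 0.75)
  expect_equal(sr$cpm, 45)
  expect_equal(stroke_rate(3, 6)$cpm, 30)
  expect_error(swim_speed(10, 0), class = "swimnet_invalid_measurement")
  expect_error(swim_speed(-10, 5), class = "swimnet_invalid_measurement")
  expect_error(stroke_rate(3, -1), class = "swimnet_invalid_measurement")
  expect_error(stroke_rate(0, 4), class = "swimnet_invalid_measurement")
})

test_that("kinematic summaries match hand-evaluated chains", {
  cases <- list(
    list(t10 = 12.5, t3 = 4.0,
         want = c(v = 0.8, sr_cpm = 45.0, sl = 0.8 / 0.75,
                  si = 0.8^2 / 0.75)),
    list(t10 = 10.0, t3 = 3.0, want = c(v = 1, sr_cpm = 60, sl = 1, si = 1)),
    list(t10 = 20.0, t3 = 5.0,
         want = c(v = 0.5, sr_cpm = 36.0, sl = 0.5 / 0.6, si = 0.25 / 0.6))
  )
  for (cs in cases) {
    k <- swim_kinematics(cs$t10, cs$t3)
    expect_equal(k$v, cs$want[["v"]])
    expect_equal(k$sr_cpm, cs$want[["sr_cpm"]])
    expect_equal(k$sl, cs$want[["sl"]], tolerance = 1e-12)
    expect_equal(k$si, cs$want[["si"]], tolerance = 1e-12)
  }
})

test_that("kinematic identities v = sl * sr and si = v * sl hold", {
  set.seed(11)
  t10 <- runif(200, 8, 25)
  t3 <- runif(200, 2.5, 8)
  k <- swim_kinematics(t10, t3)
  expect_lt(max(abs(k$sl * k$sr_cps - k$v)), 1e-9)
  expect_lt(max(abs(k$si - k$v * k$sl)), 1e-9)
  expect_true(all(unlist(k) > 0))
})

test_that("maturity offset matches frozen hand-derived values", {
  boy <- maturity_offset("M", 10.5, 145, 76, 38)
  expect_equal(boy$leg_length, 69)
  expect_equal(boy$offset, -2.661738, tolerance = 1e-6)
  girl <- maturity_offset("F", 10, 140, 74, 34)
  expect_equal(girl$leg_length, 66)
  expect_equal(girl$offset, -1.713471, tolerance = 1e-6)
  # same boy later in childhood is closer to PHV
  expect_gt(maturity_offset("M", 14.5, 145, 76, 38)$offset, boy$offset)
  expect_error(maturity_offset("M", 10, 140, 150, 38),
               class = "swimnet_invalid_anthropometrics")
  expect_error(maturity_offset("X", 10, 140, 74, 38),
               class = "swimnet_invalid_anthropometrics")
  expect_error(maturity_offset("F", -1, 140, 74, 34),
               class = "swimnet_invalid_anthropometrics")
})

test_that("maturity offset agrees with a term-by-term re-derivation", {
  set.seed(21)
  for (i in 1:200) {
    sex <- sample(c("F", "M"), 1)
    h <- runif(1, 125, 170)
    sh <- runif(1, 65, 90)
    a <- runif(1, 8, 14)
    bm <- runif(1, 25, 60)
    expect_equal(maturity_offset(sex, a, h, sh, bm)$offset,
                 oracle_maturity_offset(sex, a, h, sh, bm),
                 tolerance = 1e-12)
  }
})

test_that("percent change is exact relative change", {
  expect_equal(percent_change(100, 110), 10)
  expect_equal(percent_change(32.0, 24.5), -23.4375)
  expect_equal(percent_change(7.3, 7.3), 0)
  set.seed(3)
  a <- runif(50, 0.5, 40)
  b <- rnorm(50)
  expect_equal(percent_change(a, b), -100 * (1 - b / a))
  expect_error(percent_change(0, 5), class = "swimnet_undefined_change")
})

test_that("change vectors compose the per-variable percent changes", {
  cohort <- tiny_cohort()
  ps <- swimnet:::pair_sessions(cohort)
  cv <- change_vector(ps$before[1, ], ps$after[1, ], "breast")
  expect_named(cv$delta,
               c("d_age", "d_height", "d_arm_span", "d_body_mass", "d_t25",
                 "d_v", "d_sr", "d_sl", "d_si", "d_mo"))
  expect_equal(cv$delta[["d_height"]],
               percent_change(ps$before$height_cm[1], ps$after$height_cm[1]))
  mo_b <- maturity_offset(ps$before$sex[1], ps$before$age_y[1],
                          ps$before$height_cm[1],
                          ps$before$sitting_height_cm[1],
                          ps$before$body_mass_kg[1])$offset
  mo_a <- maturity_offset(ps$after$sex[1], ps$after$age_y[1],
                          ps$after$height_cm[1],
                          ps$after$sitting_height_cm[1],
                          ps$after$body_mass_kg[1])$offset
  expect_equal(cv$delta[["d_mo"]], percent_change(mo_b, mo_a))
  # identical sessions give all-zero change
  cv0 <- change_vector(ps$before[2, ], ps$before[2, ], "fly")
  expect_true(all(cv0$delta == 0))
  # pairing and missing-trial errors
  expect_error(change_vector(ps$before[1, ], ps$after[2, ], "breast"),
               class = "swimnet_pairing_error")
  broken <- ps$after[1, ]
  broken$fly_t10_s <- NA
  expect_error(change_vector(ps$before[1, ], broken, "fly"),
               class = "swimnet_pairing_error")
})

test_that("the change matrix has the published node layout", {
  cohort <- tiny_cohort()
  x <- change_matrix(cohort, "breast")
  expect_equal(colnames(x),
               c("gender", "d_age", "d_height", "d_arm_span", "d_body_mass",
                 "d_t25", "d_v", "d_sr", "d_sl", "d_si", "d_mo"))
  expect_equal(attr(x, "groups"), c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2, 3))
  expect_equal(nrow(x), 8)
  expect_true(all(x[, "gender"] %in% c(1, 2)))
  expect_false(anyNA(x))
})
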