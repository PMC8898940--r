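#' Hedges' g for a before/after comparison
#'
#' Standardized mean difference computed from the two group summaries,
#' `g = |m2 - m1| / sqrt((s1^2 + s2^2) / 2)`: the absolute mean difference
#' over the root mean of the two variances, without small-sample
#' correction. This uncorrected pooled-SD form is the one that reproduces
#' published age-group swimming effect sizes such as 7.5/5.945 = 1.26 for
#' a 25-m breaststroke time improving from 32.0 +/- 7.5 s to
#' 24.5 +/- 3.8 s.
#'
#' @param mean_before,sd_before Baseline mean and SD.
#' @param mean_after,sd_after Follow-up mean and SD.
#' @return Non-negative effect size g.
#' @seealso [effect_magnitude()] for the Hopkins interpretation bands.
#' @examples
#' hedges_g(32.0, 7.5, 24.5, 3.8) # 1.26
#' @export
hedges_g <- function(mean_before, sd_before, mean_after, sd_after) {
  if (any(c(sd_before, sd_after) < 0)) {
    swim_stop("standard deviations must be non-negative",
              "swimnet_domain_error")
  }
  if (all(c(sd_before, sd_after) == 0)) {
    swim_stop("both standard deviations are zero: effect size undefined",
              "swimnet_degenerate_spread")
  }
  abs(mean_after - mean_before) / sqrt((sd_before^2 + sd_after^2) / 2)
}

#' Hopkins magnitude label for an effect size
#'
#' Bands: 0-0.19 trivial, 0.2-0.59 small, 0.6-1.19 moderate, 1.2-1.99
#' large, 2.0-3.99 very large, >= 4.0 nearly perfect. Band edges belong to
#' the upper band (g = 0.2 is "small").
#'
#' @param g Non-negative effect size (vectorized).
#' @return Character vector of magnitude labels.
#' @examples
#' effect_magnitude(c(0.16, 1.26)) # "trivial" "large"
#' @export
effect_magnitude <- function(g) {
  if (any(!is.finite(g)) || any(g < 0)) {
    swim_stop("effect size must be a non-negative number",
              "swimnet_domain_error")
  }
  labels <- c("trivial", "small", "moderate", "large", "very large",
              "nearly perfect")
  labels[findInterval(g, c(0, 0.2, 0.6, 1.2, 2.0, 4.0))]
}

#' 95% confidence interval of a mean
#'
#' Student-t interval `mean +/- t(0.975, n-1) * sd / sqrt(n)`.
#' `ci95()` computes it from a sample, `ci95_stats()` from the summary
#' statistics.
#'
#' @param x Numeric sample, length >= 2.
#' @return Numeric vector `c(lo, hi)`.
#' @examples
#' ci95_stats(10.2, 1.2, 20) # (9.64, 10.76)
#' @export
ci95 <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) {
    swim_stop("at least two observations are needed for a confidence interval",
              "swimnet_insufficient_sample")
  }
  ci95_stats(mean(x), sd(x), length(x))
}

#' @rdname ci95
#' @param m,s,n Sample mean, SD and size.
#' @export
ci95_stats <- function(m, s, n) {
  if (n < 2L || s < 0) {
    swim_stop("need n >= 2 and sd >= 0", "swimnet_insufficient_sample")
  }
  half <- qt(0.975, n - 1) * s / sqrt(n)
  c(lo = m - half, hi = m + half)
}

#' Paired-samples t-test
#'
#' Two-sided paired t-test on the per-swimmer differences
#' `d = after - before`: `t = mean(d) / (sd(d) / sqrt(n))` on n - 1
#' degrees of freedom.
#'
#' @param before,after Equal-length numeric vectors of paired observations.
#' @return A list with `t`, `df` and `p`.
#' @examples
#' paired_t(c(1, 2, 3), c(2, 4, 3))
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after) || length(before) < 2L) {
    swim_stop("paired test needs two equal-length vectors with n >= 2",
              "swimnet_insufficient_sample")
  }
  d <- after - before
  if (sd(d) == 0) {
    swim_stop("differences have zero variance: paired t is undefined",
              "swimnet_degenerate_differences")
  }
  ht <- t.test(after, before, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Shapiro-Wilk normality gate
#'
#' Runs the Shapiro-Wilk test and emits a warning when normality is
#' rejected at 0.05. The gate is advisory only: it never switches the
#' downstream comparison away from the paired t-test, it just flags the
#' variable in logs.
#'
#' @param x Numeric sample, 3 <= n <= 5000, non-constant.
#' @return A list with the `W` statistic and `p` value.
#' @export
shapiro_gate <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) {
    swim_stop("Shapiro-Wilk needs at least 3 observations",
              "swimnet_insufficient_sample")
  }
  if (sd(x) == 0) {
    swim_stop("constant sample: Shapiro-Wilk W is undefined",
              "swimnet_degenerate_input")
  }
  ht <- shapiro.test(x)
  if (ht$p.value < 0.05) {
    warning(sprintf("normality rejected (Shapiro-Wilk p = %.3g)",
                    ht$p.value), call. = FALSE)
  }
  list(W = unname(ht$statistic), p = unname(ht$p.value))
}

# Variable extractors for the effect table: each returns the per-swimmer
# values of one reported variable from a session data frame.
effect_table_variables <- function(techniques) {
  anthro <- list(
    age       = function(s) s$age_y,
    height    = function(s) s$height_cm,
    arm_span  = function(s) s$arm_span_cm,
    body_mass = function(s) s$body_mass_kg,
    mo        = function(s) maturity_offset(s$sex, s$age_y, s$height_cm,
                                            s$sitting_height_cm,
                                            s$body_mass_kg)$offset
  )
  vars <- data.frame(variable = names(anthro), technique = NA_character_,
                     stringsAsFactors = FALSE)
  vars$fn <- anthro
  for (tech in techniques) {
    kin <- list(
      t25 = local({ tc <- tech; function(s) s[[paste0(tc, "_t25_s")]] }),
      v   = local({ tc <- tech; function(s) kin_of(s, tc)$v }),
      sr  = local({ tc <- tech; function(s) kin_of(s, tc)$sr_cpm }),
      sl  = local({ tc <- tech; function(s) kin_of(s, tc)$sl }),
      si  = local({ tc <- tech; function(s) kin_of(s, tc)$si })
    )
    block <- data.frame(variable = names(kin), technique = tech,
                        stringsAsFactors = FALSE)
    block$fn <- kin
    vars <- rbind(vars, block)
  }
  vars
}

kin_of <- function(s, technique) {
  swim_kinematics(t10 = s[[paste0(technique, "_t10_s")]],
                  t3cycles = s[[paste0(technique, "_t3cycles_s")]])
}

#' Seasonal effect-size table
#'
#' Summarizes a paired cohort the way longitudinal training-season studies
#' report it: one row per variable (anthropometrics and maturity offset,
#' then per-technique 25-m time, speed, stroke rate, stroke length, stroke
#' index), each with before/after mean +/- SD and 95% CI, the paired
#' t-test p-value, Hedges' g with its Hopkins magnitude label, and the
#' mean +/- SD of the individual percent changes. Normality of the paired
#' differences is checked with a Shapiro-Wilk gate that warns but never
#' switches the test.
#'
#' @param cohort Cohort table with both sessions for every swimmer.
#' @param techniques Character vector of techniques to summarize.
#' @return A data frame with one row per `EffectSizeRow`: columns
#'   `variable`, `technique`, `mean_before`, `sd_before`, `ci95_before_lo`,
#'   `ci95_before_hi`, the `_after` counterparts, `p_value`, `g`,
#'   `magnitude`, `delta_mean`, `delta_sd`.
#' @export
effect_table <- function(cohort, techniques = c("breast", "fly")) {
  techniques <- match.arg(techniques, several.ok = TRUE)
  ps <- pair_sessions(cohort)
  n <- nrow(ps$before)
  if (n < 2L) {
    swim_stop("effect summaries need at least two paired swimmers",
              "swimnet_insufficient_sample")
  }
  vars <- effect_table_variables(techniques)
  rows <- lapply(seq_len(nrow(vars)), function(i) {
    fn <- vars$fn[[i]]
    b <- fn(ps$before)
    a <- fn(ps$after)
    tt <- tryCatch(paired_t(b, a), swimnet_degenerate_differences = function(e) {
      warning(sprintf("%s: %s", vars$variable[i], conditionMessage(e)),
              call. = FALSE)
      list(t = NA_real_, df = n - 1, p = NA_real_)
    })
    if (!is.na(tt$p)) {
      withCallingHandlers(
        tryCatch(shapiro_gate(a - b), swimnet_error = function(e) NULL),
        warning = function(w) {
          warning(sprintf("%s%s: %s", vars$variable[i],
                          if (is.na(vars$technique[i])) "" else
                            paste0(" (", vars$technique[i], ")"),
                          conditionMessage(w)), call. = FALSE)
          invokeRestart("muffleWarning")
        })
    }
    g <- hedges_g(mean(b), sd(b), mean(a), sd(a))
    dl <- percent_change(b, a)
    cib <- ci95(b)
    cia <- ci95(a)
    data.frame(
      variable = vars$variable[i], technique = vars$technique[i],
      mean_before = mean(b), sd_before = sd(b),
      ci95_before_lo = cib[["lo"]], ci95_before_hi = cib[["hi"]],
      mean_after = mean(a), sd_after = sd(a),
      ci95_after_lo = cia[["lo"]], ci95_after_hi = cia[["hi"]],
      p_value = tt$p, g = g, magnitude = effect_magnitude(g),
      delta_mean = mean(dl), delta_sd = sd(dl),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
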