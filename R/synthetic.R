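# Synthetic data: (a) Gaussian samples from known sparse precision
# matrices, the ground truth for validating the network estimator, and
# (b) longitudinal swimmer cohorts with the summary structure of a
# 47-week age-group season, the ground truth for the full pipeline.

#' Sample from a known sparse Gaussian graphical model
#'
#' Builds a random sparse partial-correlation structure -- a unit-diagonal
#' precision matrix whose off-diagonal entries are minus the desired
#' partial correlations -- resampling the edge set and signs until the
#' matrix is positive-definite, so the configured magnitudes are realized
#' exactly. The precision matrix is inverted to a covariance and `n`
#' multivariate-normal rows are drawn.
#'
#' @param p Number of variables (>= 2).
#' @param edge_density Fraction of the `p (p - 1) / 2` node pairs carrying
#'   an edge, in `[0, 1]`.
#' @param pcor_range Length-2 range of absolute partial correlations,
#'   within (0, 1); signs are random.
#' @param n Number of observations (>= 2).
#' @param seed Integer seed; identical seeds give identical output.
#' @param max_tries Resampling attempts before giving up.
#' @return A list with `truth` (list: `theta`, `pcor`, `edges` data frame
#'   with `node_a`, `node_b`, `pcor`) and `data` (n x p matrix).
#' @export
sample_ggm <- function(p, edge_density, pcor_range = c(0.3, 0.4), n, seed,
                       max_tries = 500L) {
  if (p < 2L || n < 2L || edge_density < 0 || edge_density > 1 ||
      length(pcor_range) != 2L || any(pcor_range <= 0) ||
      any(pcor_range >= 1) || pcor_range[1] > pcor_range[2]) {
    swim_stop("invalid Gaussian graphical model configuration",
              "swimnet_config_error")
  }
  set.seed(as.integer(seed))
  m <- p * (p - 1L) / 2L
  n_edges <- round(edge_density * m)
  ut <- which(upper.tri(matrix(0, p, p)))
  theta <- NULL
  for (try in seq_len(max_tries)) {
    M <- matrix(0, p, p)
    if (n_edges > 0) {
      pick <- sample(m, n_edges)
      mags <- runif(n_edges, pcor_range[1], pcor_range[2])
      signs <- sample(c(-1, 1), n_edges, replace = TRUE)
      M[ut[pick]] <- -signs * mags
    }
    M <- M + t(M)
    diag(M) <- 1
    if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) > 1e-3) {
      theta <- M
      break
    }
  }
  if (is.null(theta)) {
    swim_stop(sprintf(
      "no positive-definite structure found in %d tries (p = %d, %d edges)",
      max_tries, p, n_edges), "swimnet_construction_error")
  }
  pcor <- precision_to_partial(theta)
  idx <- which(upper.tri(pcor) & abs(pcor) > 1e-12, arr.ind = TRUE)
  edges <- data.frame(node_a = idx[, 1], node_b = idx[, 2],
                      pcor = pcor[idx])
  sigma <- solve(theta)
  sigma <- (sigma + t(sigma)) / 2
  x <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = sigma)
  colnames(x) <- paste0("V", seq_len(p))
  list(truth = list(theta = theta, pcor = pcor, edges = edges), data = x)
}

#' Configuration of the synthetic swimmer cohort
#'
#' Defaults emulate a published 47-week age-group season: 11 girls
#' (10.0 +/- 1.3 y) and 9 boys (10.5 +/- 0.9 y); baseline anthropometrics
#' and per-technique kinematics drawn from the reported group
#' means +/- SD; per-variable percent-change targets (mean +/- SD of the
#' individual seasonal changes) for the directly generated variables
#' (age, height, arm span, body mass, and speed and stroke rate per
#' technique). T25, stroke length, stroke index and maturity offset are
#' derived quantities: their changes emerge from the kinematic and
#' anthropometric identities rather than being set independently.
#'
#' Each swimmer carries one latent maturation-tempo factor; each
#' variable's change loads on it with the configured loading in `[0, 1]`
#' (remaining variance is independent noise), which is what couples
#' growth, maturation and kinematic changes into a non-trivial
#' partial-correlation network. Sitting height is generated as a fixed
#' per-swimmer fraction of stature (default ratio 0.52 +/- 0.015, a
#' plausible pediatric value) so that the maturity-offset equations have
#' inputs. The 25-m time is tied to the mid-pool split by a per-swimmer
#' pacing factor, `t25 = t10 * pace * (1 + session noise)`, keeping
#' `t10 < t25` while leaving T25 partially independent of mid-pool speed.
#'
#' @param ... Named overrides of any default component.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    n_girls = 11L, n_boys = 9L, seed = 1L,
    age_girls = c(mean = 10.0, sd = 1.3),
    age_boys = c(mean = 10.5, sd = 0.9),
    before = list(
      height = c(mean = 142.3, sd = 9.7),
      arm_span = c(mean = 143.6, sd = 10.4),
      body_mass = c(mean = 36.7, sd = 8.2),
      v_breast = c(mean = 0.71, sd = 0.12),
      sr_breast = c(mean = 45.9, sd = 11.9),
      v_fly = c(mean = 0.76, sd = 0.18),
      sr_fly = c(mean = 37.1, sd = 9.7)
    ),
    change = list(
      age = c(mean = 8.9, sd = 1.3),
      height = c(mean = 3.8, sd = 1.4),
      arm_span = c(mean = 4.9, sd = 1.8),
      body_mass = c(mean = 12.1, sd = 6.7),
      v_breast = c(mean = 28.5, sd = 19.7),
      sr_breast = c(mean = 26.7, sd = 44.1),
      v_fly = c(mean = 41.0, sd = 25.3),
      sr_fly = c(mean = 16.3, sd = 23.0)
    ),
    loadings = c(age = 0.2, height = 0.7, arm_span = 0.7, body_mass = 0.6,
                 v_breast = 0.5, sr_breast = 0.5, v_fly = 0.5,
                 sr_fly = 0.5),
    sitting_height_ratio = 0.52,
    sitting_height_ratio_sd = 0.015,
    pace_factor = 2.5,
    pace_sd = 0.05,
    session_pace_sd = 0.02
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) {
    swim_stop(sprintf("unknown configuration field(s): %s",
                      paste(bad, collapse = ", ")), "swimnet_config_error")
  }
  cfg <- modifyList(cfg, over)
  if (any(unlist(cfg$loadings) < 0) || any(unlist(cfg$loadings) > 1)) {
    swim_stop("loadings must lie in [0, 1]", "swimnet_config_error")
  }
  sds <- c(vapply(cfg$before, `[[`, 0, "sd"),
           vapply(cfg$change, `[[`, 0, "sd"),
           cfg$age_girls[["sd"]], cfg$age_boys[["sd"]])
  if (any(sds < 0)) {
    swim_stop("standard deviations must be non-negative",
              "swimnet_config_error")
  }
  structure(cfg, class = "cohort_config")
}

# Percent-change scores for one variable: loading * latent factor plus
# independent noise, standardized to have exactly the target mean and SD
# in the generated sample. Whole-vector rejection keeps every change
# above -95% so multiplicative after-values remain positive.
calibrated_delta <- function(latent, loading, target, max_tries = 100L) {
  n <- length(latent)
  for (try in seq_len(max_tries)) {
    z <- loading * latent + sqrt(1 - loading^2) * rnorm(n)
    s <- sd(z)
    z <- if (s > 0) (z - mean(z)) / s else rep(0, n)
    d <- target[["mean"]] + target[["sd"]] * z
    if (all(d > -95)) return(d)
  }
  swim_stop("could not generate admissible percent changes",
            "swimnet_construction_error")
}

#' Simulate a paired longitudinal swimmer cohort
#'
#' Generates the before session of every swimmer from the configured
#' baseline distributions, the seasonal percent changes from a latent
#' maturation-tempo factor (see [cohort_config()]), and the after session
#' as `before * (1 + change / 100)`. Trial timings are solved back from
#' the drawn speed and stroke rate (`t10 = 10 / v`,
#' `t3cycles = 180 / SR`), so every generated session satisfies the
#' kinematic identities and input invariants (`t10 < t25`,
#' sitting height < stature, positive times).
#'
#' @param config A [cohort_config()] (or a list of overrides passed to
#'   it).
#' @return A list with `cohort` (data frame in the standard input layout,
#'   two rows per swimmer) and `truth` (list: `latent_factor` per swimmer,
#'   `config`).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, as.list(config))
  }
  n_girls <- as.integer(config$n_girls)
  n_boys <- as.integer(config$n_boys)
  n <- n_girls + n_boys
  if (n == 0L) {
    swim_stop("empty cohort: n_girls + n_boys must be positive",
              "swimnet_config_error")
  }
  if (n < 2L) {
    swim_stop("cohort generation needs at least two swimmers",
              "swimnet_config_error")
  }
  set.seed(as.integer(config$seed))
  sex <- c(rep("F", n_girls), rep("M", n_boys))
  rnorm_pos <- function(n, ms, floor_at) {
    pmax(rnorm(n, ms[["mean"]], ms[["sd"]]), floor_at)
  }
  age <- c(rnorm_pos(n_girls, config$age_girls, 5),
           rnorm_pos(n_boys, config$age_boys, 5))
  before <- list(
    age = age,
    height = rnorm_pos(n, config$before$height, 100),
    arm_span = rnorm_pos(n, config$before$arm_span, 100),
    body_mass = rnorm_pos(n, config$before$body_mass, 15),
    v_breast = rnorm_pos(n, config$before$v_breast, 0.3),
    sr_breast = rnorm_pos(n, config$before$sr_breast, 15),
    v_fly = rnorm_pos(n, config$before$v_fly, 0.3),
    sr_fly = rnorm_pos(n, config$before$sr_fly, 15)
  )
  latent <- rnorm(n)
  delta <- lapply(names(config$change), function(v) {
    calibrated_delta(latent, config$loadings[[v]], config$change[[v]])
  })
  names(delta) <- names(config$change)
  after <- lapply(names(before), function(v) {
    before[[v]] * (1 + delta[[v]] / 100)
  })
  names(after) <- names(before)
  sh_ratio <- pmin(pmax(rnorm(n, config$sitting_height_ratio,
                              config$sitting_height_ratio_sd), 0.45), 0.6)
  pace <- list(
    breast = pmax(config$pace_factor * (1 + rnorm(n, 0, config$pace_sd)), 1.2),
    fly = pmax(config$pace_factor * (1 + rnorm(n, 0, config$pace_sd)), 1.2)
  )
  session_row <- function(vals, session) {
    t10_b <- 10 / vals$v_breast
    t10_f <- 10 / vals$v_fly
    data.frame(
      swimmer_id = sprintf("S%03d", seq_len(n)),
      session = session,
      sex = sex,
      age_y = vals$age,
      height_cm = vals$height,
      sitting_height_cm = sh_ratio * vals$height,
      arm_span_cm = vals$arm_span,
      body_mass_kg = vals$body_mass,
      breast_t25_s = t10_b * pace$breast *
        pmax(1 + rnorm(n, 0, config$session_pace_sd), 1.05),
      breast_t10_s = t10_b,
      breast_t3cycles_s = 180 / vals$sr_breast,
      fly_t25_s = t10_f * pace$fly *
        pmax(1 + rnorm(n, 0, config$session_pace_sd), 1.05),
      fly_t10_s = t10_f,
      fly_t3cycles_s = 180 / vals$sr_fly,
      stringsAsFactors = FALSE
    )
  }
  cohort <- rbind(session_row(before, "before"), session_row(after, "after"))
  rownames(cohort) <- NULL
  list(cohort = cohort,
       truth = list(latent_factor = latent, delta = delta, config = config))
}
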