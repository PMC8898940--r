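#' Mid-pool swimming speed
#'
#' Clean swimming speed computed from a timed mid-pool split, `v = d / t`.
#' In the standard 25-m trial protocol the split is the intermediate 10 m,
#' free of start, turn and wall effects.
#'
#' @param distance Split distance in metres (default 10).
#' @param time Time to cover the split, in seconds.
#' @return Speed in m/s. Vectorized over its arguments.
#' @examples
#' swim_speed(10, 12.5) # 0.8 m/s
#' @export
swim_speed <- function(distance = 10, time) {
  if (any(!is.finite(distance)) || any(!is.finite(time)) ||
      any(distance <= 0) || any(time <= 0)) {
    swim_stop("distance and time must be positive finite numbers",
              "swimnet_invalid_measurement")
  }
  distance / time
}

#' Stroke rate from a timed block of stroke cycles
#'
#' Stroke rate is the number of stroke cycles divided by the time taken to
#' complete them; the per-minute form (cycles/min) is the one conventionally
#' reported, the per-second form is the one entering stroke-length
#' computation.
#'
#' @param n_cycles Number of consecutive stroke cycles timed (default 3).
#' @param time Time for the block of cycles, in seconds.
#' @return A list with components `cps` (cycles per second) and
#'   `cpm` (cycles per minute, `60 * cps`).
#' @examples
#' stroke_rate(3, 4) # 0.75 cps, 45 cpm
#' @export
stroke_rate <- function(n_cycles = 3, time) {
  if (any(!is.finite(n_cycles)) || any(n_cycles < 1)) {
    swim_stop("n_cycles must be >= 1", "swimnet_invalid_measurement")
  }
  if (any(!is.finite(time)) || any(time <= 0)) {
    swim_stop("time must be a positive finite number",
              "swimnet_invalid_measurement")
  }
  cps <- n_cycles / time
  list(cps = cps, cpm = 60 * cps)
}

#' Stroke kinematics from trial timings
#'
#' Derives the four standard stroke-kinematic variables from the raw
#' stopwatch measurements of a 25-m all-out trial: speed `v` from the
#' intermediate 10-m split, stroke rate `SR` from the time of three
#' consecutive stroke cycles, stroke length `SL = v / SR` (distance per
#' cycle) and stroke index `SI = v * SL` (an indirect efficiency measure).
#'
#' @param t10 Time for the intermediate 10 m, seconds.
#' @param t3cycles Time for three consecutive stroke cycles, seconds.
#' @param distance Split distance (m), default 10.
#' @param n_cycles Number of timed cycles, default 3.
#' @return A list with components `v` (m/s), `sr_cps` (cycles/s),
#'   `sr_cpm` (cycles/min), `sl` (m) and `si` (m^2/s). Vectorized.
#' @examples
#' swim_kinematics(t10 = 12.5, t3cycles = 4)
#' @export
swim_kinematics <- function(t10, t3cycles, distance = 10, n_cycles = 3) {
  v <- swim_speed(distance, t10)
  sr <- stroke_rate(n_cycles, t3cycles)
  sl <- v / sr$cps
  list(v = v, sr_cps = sr$cps, sr_cpm = sr$cpm, sl = sl, si = v * sl)
}

#' Somatic maturity offset (years from peak height velocity)
#'
#' Sex-specific anthropometric prediction of the time from age at peak
#' height velocity (PHV), the Mirwald maturity-offset equations. A negative
#' offset means the swimmer has not yet reached PHV; a positive offset,
#' years elapsed since PHV. Leg length is estimated as stature minus
#' sitting height.
#'
#' For boys:
#' `MO = -9.236 + 0.0002708 (LL*SH) - 0.001663 (A*LL) + 0.007216 (A*SH)
#'  + 0.02292 (BM/HE * 100)`
#' and for girls:
#' `MO = -9.376 + 0.0001882 (LL*SH) + 0.0022 (A*LL) + 0.005847 (A*SH)
#'  - 0.002658 (A*BM) + 0.07693 (BM/HE * 100)`
#' with `LL` leg length (cm), `SH` sitting height (cm), `A` decimal age
#' (years), `BM` body mass (kg), `HE` stature (cm); the mass term is the
#' mass-to-stature ratio scaled by 100.
#'
#' @param sex Character vector, `"F"`/`"girl"` or `"M"`/`"boy"`
#'   (case-insensitive).
#' @param age Decimal age, years.
#' @param height Stature, cm.
#' @param sitting_height Sitting height, cm; must be below stature.
#' @param body_mass Body mass, kg.
#' @return A list with components `offset` (years, negative = pre-PHV) and
#'   `leg_length` (cm). Vectorized.
#' @examples
#' maturity_offset("M", age = 10.5, height = 145, sitting_height = 76,
#'                 body_mass = 38)
#' @export
maturity_offset <- function(sex, age, height, sitting_height, body_mass) {
  sex <- normalize_sex(sex)
  num <- cbind(age, height, sitting_height, body_mass)
  if (any(!is.finite(num)) || any(num <= 0)) {
    swim_stop("age, height, sitting height and body mass must be positive",
              "swimnet_invalid_anthropometrics")
  }
  if (any(sitting_height >= height)) {
    swim_stop("sitting height must be smaller than stature",
              "swimnet_invalid_anthropometrics")
  }
  ll <- height - sitting_height
  wh <- (body_mass / height) * 100
  boys <- -9.236 +
    0.0002708 * (ll * sitting_height) -
    0.001663 * (age * ll) +
    0.007216 * (age * sitting_height) +
    0.02292 * wh
  girls <- -9.376 +
    0.0001882 * (ll * sitting_height) +
    0.0022 * (age * ll) +
    0.005847 * (age * sitting_height) -
    0.002658 * (age * body_mass) +
    0.07693 * wh
  list(offset = ifelse(sex == "M", boys, girls), leg_length = ll)
}

# Map sex labels to "F"/"M"; errors on anything else.
normalize_sex <- function(sex) {
  s <- toupper(as.character(sex))
  s[s %in% c("F", "GIRL", "FEMALE")] <- "F"
  s[s %in% c("M", "BOY", "MALE")] <- "M"
  if (any(!s %in% c("F", "M"))) {
    swim_stop("sex must be one of F/girl or M/boy",
              "swimnet_invalid_anthropometrics")
  }
  s
}

#' Relative change in percent
#'
#' `100 * (after - before) / before`. Note that for a quantity crossing
#' zero (such as the maturity offset around PHV) the denominator is close
#' to zero and the percent change can be extreme or sign-flipped; no
#' winsorization is applied.
#'
#' @param before Baseline value, must be non-zero.
#' @param after Follow-up value.
#' @return Percent change. Vectorized.
#' @examples
#' percent_change(100, 110) # 10
#' @export
percent_change <- function(before, after) {
  if (any(!is.finite(before)) || any(!is.finite(after)) || any(before == 0)) {
    swim_stop("percent change is undefined for a zero or non-finite baseline",
              "swimnet_undefined_change")
  }
  100 * (after - before) / before
}

# gender coding used throughout the network input: 1 = girls, 2 = boys
gender_code <- function(sex) ifelse(normalize_sex(sex) == "F", 1, 2)

# Variables of a change vector, in the column order of the reported
# weight matrices: group 1 (gender + anthropometrics), group 2
# (performance/kinematics), group 3 (maturation).
change_variables <- function() {
  c("gender", "d_age", "d_height", "d_arm_span", "d_body_mass",
    "d_t25", "d_v", "d_sr", "d_sl", "d_si", "d_mo")
}

change_groups <- function() c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2, 3)

#' Per-swimmer seasonal change vector
#'
#' Builds the percent-change vector of one swimmer between two measurement
#' sessions for one technique: gender code (1 = girls, 2 = boys) plus the
#' relative change of age, height, arm span, body mass, 25-m time, speed,
#' stroke rate, stroke length, stroke index and maturity offset. The
#' maturity-offset change is the percent change of the offset itself, which
#' is extreme for swimmers whose offset is near zero.
#'
#' @param before,after Single-session records for the same swimmer: lists
#'   or one-row data frames with fields `swimmer_id`, `sex`, `age_y`,
#'   `height_cm`, `sitting_height_cm`, `arm_span_cm`, `body_mass_kg` and,
#'   per technique `x`, `x_t25_s`, `x_t10_s`, `x_t3cycles_s`.
#' @param technique `"breast"` or `"fly"`.
#' @return A list with `swimmer_id`, `gender_code` and `delta`, a named
#'   numeric vector over the ten change variables.
#' @export
change_vector <- function(before, after, technique = c("breast", "fly")) {
  technique <- match.arg(technique)
  before <- as.list(before)
  after <- as.list(after)
  if (!identical(as.character(before$swimmer_id),
                 as.character(after$swimmer_id))) {
    swim_stop(sprintf("session pairing mismatch: '%s' vs '%s'",
                      before$swimmer_id, after$swimmer_id),
              "swimnet_pairing_error")
  }
  cols <- paste0(technique, c("_t25_s", "_t10_s", "_t3cycles_s"))
  for (s in list(before, after)) {
    vals <- unlist(s[cols])
    if (length(vals) < 3L || any(is.na(vals))) {
      swim_stop(sprintf("swimmer '%s' is missing %s trial timings",
                        s$swimmer_id, toupper(technique)),
                "swimnet_pairing_error")
    }
  }
  kin <- lapply(list(before, after), function(s) {
    swim_kinematics(t10 = s[[cols[2]]], t3cycles = s[[cols[3]]])
  })
  mo <- lapply(list(before, after), function(s) {
    maturity_offset(s$sex, s$age_y, s$height_cm, s$sitting_height_cm,
                    s$body_mass_kg)$offset
  })
  delta <- c(
    d_age       = percent_change(before$age_y, after$age_y),
    d_height    = percent_change(before$height_cm, after$height_cm),
    d_arm_span  = percent_change(before$arm_span_cm, after$arm_span_cm),
    d_body_mass = percent_change(before$body_mass_kg, after$body_mass_kg),
    d_t25       = percent_change(before[[cols[1]]], after[[cols[1]]]),
    d_v         = percent_change(kin[[1]]$v, kin[[2]]$v),
    d_sr        = percent_change(kin[[1]]$sr_cpm, kin[[2]]$sr_cpm),
    d_sl        = percent_change(kin[[1]]$sl, kin[[2]]$sl),
    d_si        = percent_change(kin[[1]]$si, kin[[2]]$si),
    d_mo        = percent_change(mo[[1]], mo[[2]])
  )
  list(swimmer_id = as.character(before$swimmer_id),
       gender_code = gender_code(before$sex),
       delta = delta)
}

# Split a cohort table into aligned before/after data frames (one row per
# swimmer, common order); errors on unpaired or duplicated sessions.
pair_sessions <- function(cohort) {
  cohort <- as.data.frame(cohort)
  if (anyDuplicated(cohort[, c("swimmer_id", "session")])) {
    dup <- cohort[duplicated(cohort[, c("swimmer_id", "session")]), ]
    swim_stop(sprintf("duplicated session rows for swimmer(s): %s",
                      paste(unique(dup$swimmer_id), collapse = ", ")),
              "swimnet_pairing_error")
  }
  before <- cohort[cohort$session == "before", , drop = FALSE]
  after <- cohort[cohort$session == "after", , drop = FALSE]
  ids <- union(before$swimmer_id, after$swimmer_id)
  missing <- ids[!(ids %in% before$swimmer_id & ids %in% after$swimmer_id)]
  if (length(missing)) {
    swim_stop(sprintf("swimmer(s) without both sessions: %s",
                      paste(missing, collapse = ", ")),
              "swimnet_pairing_error")
  }
  before <- before[order(before$swimmer_id), , drop = FALSE]
  after <- after[order(after$swimmer_id), , drop = FALSE]
  rownames(before) <- rownames(after) <- NULL
  list(before = before, after = after)
}

#' Cohort change matrix for network estimation
#'
#' Assembles the n-by-p observation matrix fed to the partial-correlation
#' network: one row per swimmer, columns `gender` (1 = girls, 2 = boys)
#' followed by the ten percent-change variables of [change_vector()] for
#' the chosen technique. Node groups (1 gender/anthropometrics,
#' 2 performance/kinematics, 3 maturation) are attached as an attribute.
#'
#' @param cohort Cohort table in the standard input layout (see
#'   [read_cohort()]), both sessions present for every swimmer.
#' @param technique `"breast"` or `"fly"`.
#' @return A numeric matrix with `attr(, "groups")` and
#'   `attr(, "technique")`; row names are swimmer ids.
#' @export
change_matrix <- function(cohort, technique = c("breast", "fly")) {
  technique <- match.arg(technique)
  ps <- pair_sessions(cohort)
  rows <- lapply(seq_len(nrow(ps$before)), function(i) {
    cv <- change_vector(ps$before[i, ], ps$after[i, ], technique)
    c(gender = cv$gender_code, cv$delta)
  })
  x <- do.call(rbind, rows)
  rownames(x) <- ps$before$swimmer_id
  colnames(x) <- change_variables()
  attr(x, "groups") <- change_groups()
  attr(x, "technique") <- technique
  x
}
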