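# Submaximal fitness tests: squat (Ruffier-Dickson) and single-stage
# treadmill walk (Ebbeling). Both are pure computations over HR traces.

# Mean of hr over the half-open window [from, to); errors name the window.
window_mean <- function(series, from, to, label) {
  sel <- series$t_sec >= from & series$t_sec < to
  if (!any(sel)) {
    cf_abort(sprintf("No samples in the %s window [%g, %g).", label, from, to))
  }
  mean(series$hr_bpm[sel])
}

window_max <- function(series, from, to, label) {
  sel <- series$t_sec >= from & series$t_sec < to
  if (!any(sel)) {
    cf_abort(sprintf("No samples in the %s window [%g, %g).", label, from, to))
  }
  max(series$hr_bpm[sel])
}

#' Extract squat-test heart-rate parameters
#'
#' The squat test is a 45-second paced (40 bends/min) squatting exercise
#' followed by a recovery period. Three parameters are read off the traces,
#' all on half-open windows at the nominal 1 Hz sampling:
#'
#' * `p0` — mean resting HR over the final 15 s before exercise onset;
#' * `p1` — maximum HR during the first 15 s of recovery (time 0 = exercise
#'   end);
#' * `p2` — mean HR over recovery seconds 60 to 75.
#'
#' @param rest_series [hr_series()] covering at least the last 15 s of rest;
#'   time is seconds from rest start.
#' @param recovery_series [hr_series()] with time 0 at exercise end, covering
#'   at least 75 s.
#' @return A one-row tibble with `p0`, `p1`, `p2` (bpm).
#' @export
extract_squat_params <- function(rest_series, recovery_series) {
  validate_hr_series(rest_series)
  validate_hr_series(recovery_series)
  rest_end <- max(rest_series$t_sec) + 1 / nominal_rate(rest_series)
  if (rest_end - min(rest_series$t_sec) < 15) {
    cf_abort("Rest trace too short: the resting window needs 15 s of coverage.")
  }
  rec_end <- max(recovery_series$t_sec) + 1 / nominal_rate(recovery_series)
  if (min(recovery_series$t_sec) > 0 || rec_end < 75) {
    cf_abort("Recovery trace must cover [0, 75) s for the recovery windows.")
  }
  tibble(
    p0 = window_mean(rest_series, rest_end - 15, rest_end, "resting (P0)"),
    p1 = window_max(recovery_series, 0, 15, "early-recovery (P1)"),
    p2 = window_mean(recovery_series, 60, 75, "late-recovery (P2)")
  )
}

#' Ruffier-Dickson index
#'
#' `RDI = ((P1 - 70) + 2 (P2 - P0)) / 10`. A heart-rate recovery index:
#' lower values indicate faster recovery and better cardiorespiratory
#' fitness. Linear in its inputs with coefficients -0.2 (P0), +0.1 (P1),
#' +0.2 (P2).
#'
#' @param p0 15-s mean resting HR, bpm.
#' @param p1 Maximum HR in the first 15 s of recovery, bpm.
#' @param p2 Mean HR over recovery seconds 60-75, bpm.
#' @return The dimensionless index (vectorized).
#' @examples
#' ruffier_dickson_index(60, 100, 70) # 5
#' @export
ruffier_dickson_index <- function(p0, p1, p2) {
  cf_assert(is.numeric(p0) && is.numeric(p1) && is.numeric(p2),
            "P0, P1, P2 must be numeric.")
  if (any(c(p0, p1, p2) <= 0)) {
    cf_abort("P0, P1 and P2 must be positive heart rates (bpm).")
  }
  ((p1 - 70) + 2 * (p2 - p0)) / 10
}

#' Score a squat test from its heart-rate traces
#'
#' Convenience wrapper: extracts (P0, P1, P2) with [extract_squat_params()]
#' and computes the [ruffier_dickson_index()].
#'
#' @inheritParams extract_squat_params
#' @return A one-row tibble of class `squat_test_result` with `p0`, `p1`,
#'   `p2`, `rdi`.
#' @export
squat_test <- function(rest_series, recovery_series) {
  params <- extract_squat_params(rest_series, recovery_series)
  out <- dplyr::mutate(params,
                       rdi = ruffier_dickson_index(.data$p0, .data$p1, .data$p2))
  structure(out, class = c("squat_test_result", class(out)))
}

#' Ebbeling single-stage treadmill walk VO2max estimate
#'
#' `VO2max = 15.1 + 21.8 speed - 0.327 HR - 0.263 speed x age
#'  + 0.00504 HR x age + 5.98 sex`, with speed in mph, HR the steady-state
#' heart rate of the 5%-incline stage, and sex coded 0 for females, 1 for
#' males (so, all else equal, males score exactly 5.98 higher).
#'
#' @param speed_mph Walking speed in miles per hour (> 0).
#' @param hr_bpm Steady-state stage heart rate, bpm.
#' @param age Age in years.
#' @param sex `"female"`/`"male"`, `"F"`/`"M"`, or the numeric coding 0/1.
#' @return Estimated VO2max in mL/kg/min (vectorized over the numeric
#'   arguments).
#' @examples
#' ebbeling_vo2max(3.4, 140, 40, "female") # 35.896
#' @export
ebbeling_vo2max <- function(speed_mph, hr_bpm, age, sex) {
  cf_assert(is.numeric(speed_mph) && is.numeric(hr_bpm) && is.numeric(age),
            "`speed_mph`, `hr_bpm`, `age` must be numeric.")
  if (any(speed_mph <= 0)) cf_abort("`speed_mph` must be positive.")
  if (any(age <= 0 | age >= 120)) cf_abort("`age` must lie in (0, 120).")
  sex_code <- sex_to_code(sex)
  15.1 + 21.8 * speed_mph - 0.327 * hr_bpm - 0.263 * speed_mph * age +
    0.00504 * hr_bpm * age + 5.98 * sex_code
}

sex_to_code <- function(sex) {
  if (is.numeric(sex)) {
    if (any(!sex %in% c(0, 1))) cf_abort("Numeric sex code must be 0 or 1.")
    return(as.double(sex))
  }
  vapply(as.character(sex),
         function(s) if (normalize_sex(s) == "male") 1 else 0,
         numeric(1), USE.NAMES = FALSE)
}

#' Check treadmill walking speed against the target heart-rate window
#'
#' The walking stage should elicit a heart rate between 50% and 75% of the
#' age-predicted maximum (220 - age), bounds included.
#'
#' @param hr_observed Observed walking HR, bpm.
#' @param age Age in years.
#' @return `TRUE` iff the HR lies inside the closed window (vectorized).
#' @examples
#' check_walk_speed(120, 40) # TRUE: window is [90, 135]
#' @export
check_walk_speed <- function(hr_observed, age) {
  hr_max <- estimate_hr_max(age)
  hr_observed >= 0.50 * hr_max & hr_observed <= 0.75 * hr_max
}

#' Steady-state decision for the incline stage
#'
#' The test ends when minute-7 and minute-8 heart rates do not differ by
#' more than 6 bpm; otherwise it is extended by one minute.
#'
#' @param hr_min7,hr_min8 Heart rates (bpm) for minutes 7 and 8.
#' @return `"end_test"` or `"extend_one_minute"`.
#' @examples
#' steady_state_decision(140, 145) # end_test
#' @export
steady_state_decision <- function(hr_min7, hr_min8) {
  cf_assert(is_number(hr_min7) && is_number(hr_min8),
            "Both minute HRs must be numbers.")
  if (abs(hr_min8 - hr_min7) <= 6) "end_test" else "extend_one_minute"
}

#' Score a treadmill walk test from its heart-rate trace
#'
#' The protocol: a 4-minute flat walk at a speed keeping HR between 50% and
#' 75% of the age-predicted maximum, then 4-5 minutes at a 5% incline at the
#' same speed. Minute HRs are 60-s window means; if minutes 7 and 8 differ by
#' more than 6 bpm the ninth minute is used (`extended`). The stage HR fed to
#' the VO2max equation is the mean over the final 60 s of the incline stage.
#'
#' @param trace [hr_series()] covering the whole test, time 0 at test start.
#' @param speed_mph Belt speed, mph. Use `kmh_to_mph()` for metric input.
#' @param age Age in years.
#' @param sex See [ebbeling_vo2max()].
#' @param incline_start_s Seconds into the test at which the incline stage
#'   starts (default 240).
#' @return A one-row tibble of class `treadmill_test_result` with `speed`,
#'   `stage_hr`, `hr_min7`, `hr_min8`, `extended`, `walk_hr_ok`, `vo2max`.
#' @export
treadmill_test <- function(trace, speed_mph, age, sex, incline_start_s = 240) {
  validate_hr_series(trace)
  walk_hr <- window_mean(trace, 0, incline_start_s, "flat-walk")
  hr_min7 <- window_mean(trace, 360, 420, "minute-7")
  hr_min8 <- window_mean(trace, 420, 480, "minute-8")
  extended <- steady_state_decision(hr_min7, hr_min8) == "extend_one_minute"
  stage_end <- if (extended) 540 else 480
  stage_hr <- window_mean(trace, stage_end - 60, stage_end, "stage-HR")
  out <- tibble(
    speed = as.double(speed_mph), stage_hr = stage_hr,
    hr_min7 = hr_min7, hr_min8 = hr_min8, extended = extended,
    walk_hr_ok = check_walk_speed(walk_hr, age),
    vo2max = ebbeling_vo2max(speed_mph, stage_hr, age, sex)
  )
  structure(out, class = c("treadmill_test_result", class(out)))
}

#' Convert km/h to miles per hour
#'
#' The VO2max regression expects speed in mph end-to-end; metric input must
#' be converted explicitly to avoid silent unit errors.
#'
#' @param kmh Speed in kilometers per hour.
#' @return Speed in miles per hour.
#' @export
kmh_to_mph <- function(kmh) kmh / 1.609344
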