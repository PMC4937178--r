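#' Define a personalized heart-rate zone
#'
#' Beats are only credited while the heart rate lies inside this zone
#' (inclusive bounds). [zone_around()] builds the zone around a Karvonen
#' target heart rate with configurable widths; the +/- 10 bpm default width
#' is a package choice, not a published value.
#'
#' @param lower,upper Zone bounds in bpm, `lower < upper`.
#' @return A one-row tibble of class `hr_zone`.
#' @examples
#' hr_zone(110, 130)
#' zone_around(120)
#' @export
hr_zone <- function(lower, upper) {
  cf_assert(is_number(lower) && is_number(upper), "Zone bounds must be numbers.")
  cf_assert(lower < upper, "`lower` must be strictly below `upper`.")
  out <- tibble(lower = as.double(lower), upper = as.double(upper))
  structure(out, class = c("hr_zone", class(out)))
}

#' @rdname hr_zone
#' @param target_hr Target heart rate the zone is centred on, bpm.
#' @param width_below,width_above Zone half-widths below/above the target, bpm.
#' @export
zone_around <- function(target_hr, width_below = 10, width_above = 10) {
  cf_assert(is_number(target_hr) && target_hr > 0, "`target_hr` must be positive.")
  cf_assert(is_number(width_below) && width_below > 0 &&
              is_number(width_above) && width_above > 0,
            "Zone widths must be positive.")
  hr_zone(target_hr - width_below, target_hr + width_above)
}

#' Count beats accumulated inside a heart-rate zone (mBeats)
#'
#' The training-load metric: the number of heart beats spent inside the
#' personalized zone. Each sample contributes `hr/60 x dt` beats (left-value
#' accounting; `dt` is the interval to the next sample, one nominal sample
#' period for the last) when its heart rate lies inside the zone, inclusive.
#' Samples flagged invalid and intervals longer than `gap_threshold` seconds
#' (recording gaps) contribute zero beats — gaps are never interpolated.
#'
#' A 30-minute session held exactly at a 120 bpm target therefore yields
#' `120 x 30 = 3600` mBeats.
#'
#' @param series An [hr_series()].
#' @param zone An [hr_zone()].
#' @param gap_threshold Seconds; see [hr_gaps()].
#' @return Beats in zone (real, >= 0); 0 for an empty series.
#' @examples
#' s <- hr_series(0:1799, rep(120, 1800))
#' count_mbeats(s, hr_zone(110, 130)) # 3600
#' @export
count_mbeats <- function(series, zone, gap_threshold = 5) {
  validate_hr_series(series)
  cf_assert(inherits(zone, "hr_zone"), "`zone` must be an hr_zone.")
  if (nrow(series) == 0) return(0)
  dt <- sample_dt(series)
  in_zone <- series$valid & series$hr_bpm >= zone$lower & series$hr_bpm <= zone$upper
  credited <- in_zone & dt <= gap_threshold
  sum(series$hr_bpm[credited] / 60 * dt[credited])
}

#' Initialize a training week
#'
#' A week is split into training days and rest days; the weekly beats-in-zone
#' target is pursued over the training days, while beats collected on rest
#' days still count toward the weekly total as bonus. Day targets are not
#' fixed: each day's target is recomputed at day start from the remaining
#' weekly target (see [adaptive_daily_target()]).
#'
#' @param weekly_target Weekly mBeats target (> 0), typically
#'   `weekly_mbeats_target` from a [prescribe()] result.
#' @param day_types Character vector of 7 day types, `"T"`/`"training"` or
#'   `"R"`/`"rest"`.
#' @return An object of class `training_week`: list with `weekly_target`,
#'   `days` (tibble `day`, `type`, `achieved`) and `current_day`.
#' @examples
#' training_week(10800, c("T", "R", "T", "R", "T", "R", "R"))
#' @export
training_week <- function(weekly_target, day_types) {
  cf_assert(is_number(weekly_target) && weekly_target > 0,
            "`weekly_target` must be positive.")
  cf_assert(length(day_types) == 7L, "`day_types` must have 7 entries.")
  key <- c(t = "training", training = "training", r = "rest", rest = "rest")
  types <- key[tolower(as.character(day_types))]
  if (anyNA(types)) cf_abort("Day types must be T/training or R/rest.")
  structure(
    list(weekly_target = as.double(weekly_target),
         days = tibble(day = 1:7, type = unname(types), achieved = NA_real_),
         current_day = 1L),
    class = "training_week")
}

#' Adaptive daily beats-in-zone target
#'
#' At the start of each day: rest days have a target of 0; a training day's
#' target is the remaining weekly target (clamped at zero once the week is
#' complete) divided equally over the remaining training days, the current
#' one included. With a 10,800 weekly target over three training days the
#' first target is 3600; after 7000 beats on day one, each of the two
#' remaining training days gets (10,800 - 7000) / 2 = 1900.
#'
#' @param week A [training_week()].
#' @param day Day index (1-7); defaults to the week's current day.
#' @return The day's mBeats target (real, >= 0). If no training days remain
#'   but target does, returns 0 with a warning (week cannot be completed).
#' @export
adaptive_daily_target <- function(week, day = week$current_day) {
  cf_assert(inherits(week, "training_week"), "`week` must be a training_week.")
  cf_assert(is_number(day) && day >= 1 && day <= 7, "`day` must be in 1..7.")
  days <- week$days
  achieved <- sum(days$achieved[seq_len(day - 1)], na.rm = TRUE)
  remaining_target <- max(week$weekly_target - achieved, 0)
  remaining_training <- sum(days$type[day:7] == "training")
  if (remaining_training == 0) {
    if (remaining_target > 0) {
      rlang::warn("No training days remain but the weekly target is unmet.")
    }
    return(0)
  }
  if (days$type[day] == "rest") return(0)
  remaining_target / remaining_training
}

#' Record a day's achieved beats
#'
#' Days must be recorded in order. Achieved beats are either counted from a
#' heart-rate stream (`series` + `zone`) or given directly (`mbeats`). Beats
#' collected on a rest day count fully toward the weekly total (bonus), so
#' they shrink the next training day's adaptive target.
#'
#' @param week A [training_week()].
#' @param day Day index; must equal the week's current day.
#' @param series Optional [hr_series()] for the day (with `zone`).
#' @param zone Optional [hr_zone()]; required with `series`.
#' @param mbeats Directly supplied achieved mBeats (alternative to `series`).
#' @param gap_threshold Passed to [count_mbeats()].
#' @return The updated `training_week`.
#' @export
record_day <- function(week, day, series = NULL, zone = NULL, mbeats = NULL,
                       gap_threshold = 5) {
  cf_assert(inherits(week, "training_week"), "`week` must be a training_week.")
  if (!is_number(day) || day != week$current_day) {
    cf_abort(sprintf("Days must be recorded in order: expected day %d, got %s.",
                     week$current_day, format(day)))
  }
  if (is.null(mbeats)) {
    if (is.null(series)) {
      mbeats <- 0
    } else {
      cf_assert(!is.null(zone), "Provide `zone` along with `series`.")
      mbeats <- count_mbeats(series, zone, gap_threshold = gap_threshold)
    }
  }
  cf_assert(is_number(mbeats) && mbeats >= 0, "`mbeats` must be non-negative.")
  week$days$achieved[day] <- as.double(mbeats)
  week$current_day <- as.integer(day + 1L)
  week
}

#' Weekly achievement as a percentage of target
#'
#' `100 x total achieved / weekly target`; can exceed 100 when the target is
#' overshot.
#'
#' @param week A [training_week()].
#' @return Percentage (real, >= 0).
#' @export
weekly_percent <- function(week) {
  cf_assert(inherits(week, "training_week"), "`week` must be a training_week.")
  if (week$weekly_target <= 0) cf_abort("Weekly target must be positive.")
  100 * sum(week$days$achieved, na.rm = TRUE) / week$weekly_target
}

#' Per-day progress report
#'
#' For each day: its type, target at day start (adaptive), achieved beats and
#' percent of target. A rest day has target 0; its percent is reported as
#' 100 when nothing was collected and its beats are shown as `bonus`
#' otherwise (the underlying numbers are unambiguous either way).
#'
#' @param week A [training_week()].
#' @return A tibble with one row per recorded day: `day`, `type`,
#'   `day_target`, `achieved`, `percent_of_target`, `bonus`.
#' @export
day_progress <- function(week) {
  cf_assert(inherits(week, "training_week"), "`week` must be a training_week.")
  recorded <- which(!is.na(week$days$achieved))
  purrr::map_dfr(recorded, function(d) {
    # reconstruct the target as it stood at that day's start
    wk <- week
    wk$days$achieved[d:7] <- NA_real_
    wk$current_day <- as.integer(d)
    tgt <- suppressWarnings(adaptive_daily_target(wk, d))
    ach <- week$days$achieved[d]
    tibble(day = d, type = week$days$type[d], day_target = tgt, achieved = ach,
           percent_of_target = if (tgt > 0) 100 * ach / tgt else 100,
           bonus = if (tgt > 0) 0 else ach)
  })
}

#' @export
print.training_week <- function(x, ...) {
  cat(sprintf("<training_week> target %.0f mBeats, day %d\n",
              x$weekly_target, x$current_day))
  print(x$days)
  invisible(x)
}

#' Tidy a training week
#' @param x A [training_week()].
#' @param ... Unused.
#' @return The [day_progress()] tibble.
#' @export
tidy.training_week <- function(x, ...) day_progress(x)

#' One-row summary of a training week
#' @param x A [training_week()].
#' @param ... Unused.
#' @return Tibble with `weekly_target`, `achieved`, `weekly_percent`,
#'   `days_recorded`.
#' @export
glance.training_week <- function(x, ...) {
  tibble(weekly_target = x$weekly_target,
         achieved = sum(x$days$achieved, na.rm = TRUE),
         weekly_percent = weekly_percent(x),
         days_recorded = sum(!is.na(x$days$achieved)))
}

#' Plot weekly progress
#'
#' Bars of achieved beats per day, coloured by day type, with each day's
#' start-of-day target overlaid.
#'
#' @param object A [training_week()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.training_week <- function(object, ...) {
  prog <- day_progress(object)
  ggplot2::ggplot(prog, ggplot2::aes(x = factor(.data$day), y = .data$achieved,
                                     fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::geom_point(ggplot2::aes(y = .data$day_target), shape = 95, size = 8,
                        colour = "black") +
    ggplot2::scale_fill_manual(values = c(training = "steelblue", rest = "grey70")) +
    ggplot2::labs(x = "Day", y = "mBeats", fill = "Day type") +
    ggplot2::theme_minimal()
}

#' Save / load training-week state as JSON
#'
#' The state round-trips exactly: day types, achieved values and the current
#' day index are preserved.
#'
#' @param week A [training_week()].
#' @param path JSON file path.
#' @return `write_week_state()` returns `path` invisibly; `read_week_state()`
#'   returns a `training_week`.
#' @export
write_week_state <- function(week, path) {
  cf_assert(inherits(week, "training_week"), "`week` must be a training_week.")
  jsonlite::write_json(
    list(weekly_target = week$weekly_target, day_types = week$days$type,
         achieved = week$days$achieved, current_day = week$current_day),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_week_state
#' @export
read_week_state <- function(path) {
  cf_assert(file.exists(path), sprintf("File not found: %s", path))
  st <- jsonlite::read_json(path, simplifyVector = TRUE)
  cf_assert(all(c("weekly_target", "day_types", "achieved", "current_day")
                %in% names(st)), "Malformed week-state file.")
  wk <- training_week(st$weekly_target, st$day_types)
  wk$days$achieved <- as.double(unlist(st$achieved))
  wk$current_day <- as.integer(st$current_day)
  wk
}
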