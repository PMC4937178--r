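#' Build an exercise prescription record directly
#'
#' Low-level constructor enforcing the defining identity of the weekly
#' beats-in-zone target: `weekly_mbeats_target = target_hr x session_minutes
#' x frequency_per_week`, exactly. Most users will call [prescribe()]
#' instead, which derives the factors from a profile and the FITT table.
#'
#' @param target_hr Target heart rate, bpm (real-valued).
#' @param session_minutes Planned session duration, minutes.
#' @param frequency_per_week Planned training sessions per week.
#' @param intensity_fraction Fraction of heart-rate reserve used to derive
#'   `target_hr` (optional, for record keeping).
#' @param hr_rest,hr_max Owning profile's resting/maximal HR (optional; when
#'   supplied, `target_hr` must lie in `(hr_rest, hr_max]`).
#' @param id Participant identifier.
#' @param category Fitness category label (optional).
#' @return A one-row tibble of class `exercise_prescription`.
#' @examples
#' exercise_prescription(target_hr = 120, session_minutes = 30,
#'                       frequency_per_week = 3)
#' @export
exercise_prescription <- function(target_hr, session_minutes, frequency_per_week,
                                  intensity_fraction = NA_real_,
                                  hr_rest = NA_real_, hr_max = NA_real_,
                                  id = NA_character_, category = NA_character_) {
  cf_assert(is_number(target_hr) && target_hr > 0, "`target_hr` must be positive.")
  cf_assert(is_number(session_minutes) && session_minutes > 0,
            "`session_minutes` must be positive.")
  cf_assert(is_number(frequency_per_week) && frequency_per_week > 0,
            "`frequency_per_week` must be positive.")
  if (is.finite(hr_rest) && is.finite(hr_max)) {
    cf_assert(hr_rest < target_hr && target_hr <= hr_max,
              "`target_hr` must satisfy hr_rest < target_hr <= hr_max.")
  }
  out <- tibble(
    id = as.character(id), category = as.character(category),
    intensity_fraction = as.double(intensity_fraction),
    target_hr = as.double(target_hr),
    session_minutes = as.double(session_minutes),
    frequency_per_week = as.double(frequency_per_week),
    weekly_mbeats_target = as.double(target_hr) * session_minutes * frequency_per_week
  )
  structure(out, class = c("exercise_prescription", class(out)))
}

#' Prescribe exercise from a profile and FITT table
#'
#' Classifies the participant (unless a classification is supplied), looks
#' the category up in the FITT table, and takes the minimum of each range —
#' the conservative starting dose: lowest admissible intensity, shortest
#' duration, fewest sessions. The target heart rate comes from the Karvonen
#' heart-rate-reserve formula and is kept real-valued; rounding to whole bpm
#' is a display concern only.
#'
#' @param profile A [participant_profile()].
#' @param classification Optional result of [classify_fitness()]; computed
#'   from `classes` when omitted.
#' @param fitt A [read_fitt_table()] result (shipped default if omitted).
#' @param classes A [read_class_table()] result (shipped default if omitted).
#' @return A one-row `exercise_prescription` tibble with the weekly
#'   beats-in-zone (mBeats) target `target_hr x session_minutes x
#'   frequency_per_week`.
#' @examples
#' p <- participant_profile(age = 30, sex = "female", hr_rest = 90, vo2max = 25)
#' prescribe(p)
#' @export
prescribe <- function(profile, classification = NULL,
                      fitt = read_fitt_table(), classes = read_class_table()) {
  cf_assert(inherits(fitt, "fitt_table"), "`fitt` must be a fitt_table.")
  classification <- classification %||% classify_fitness(profile, classes)
  category <- as.character(classification$category[[1]])
  row <- dplyr::filter(fitt, .data$category == !!category)
  if (nrow(row) == 0) {
    cf_abort(sprintf("Category `%s` is absent from the FITT table.", category))
  }
  target_hr <- karvonen_target_hr(profile$hr_max, profile$hr_rest,
                                  row$intensity_min)
  exercise_prescription(
    target_hr = target_hr, session_minutes = row$duration_min,
    frequency_per_week = row$frequency_min,
    intensity_fraction = row$intensity_min,
    hr_rest = profile$hr_rest, hr_max = profile$hr_max,
    id = profile$id, category = category
  )
}

#' @export
print.exercise_prescription <- function(x, ...) {
  cat("<exercise_prescription>\n")
  cat(sprintf("  participant : %s (%s)\n", x$id, x$category))
  cat(sprintf("  intensity   : %s of HRR\n",
              ifelse(is.na(x$intensity_fraction), "-",
                     sprintf("%.0f%%", 100 * x$intensity_fraction))))
  cat(sprintf("  target HR   : %.0f bpm\n", round(x$target_hr)))
  cat(sprintf("  dose        : %g min x %g sessions/week\n",
              x$session_minutes, x$frequency_per_week))
  cat(sprintf("  weekly goal : %.0f mBeats\n", round(x$weekly_mbeats_target)))
  invisible(x)
}

#' Tidy an exercise prescription
#' @param x An `exercise_prescription`.
#' @param ... Unused.
#' @return A long tibble with `term` and `value` columns.
#' @export
tidy.exercise_prescription <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::select(as_tibble(x), "intensity_fraction":"weekly_mbeats_target"),
    dplyr::everything(), names_to = "term", values_to = "value")
}

#' One-row summary of an exercise prescription
#' @param x An `exercise_prescription`.
#' @param ... Unused.
#' @return The underlying one-row tibble.
#' @export
glance.exercise_prescription <- function(x, ...) as_tibble(x)
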