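#' Build a heart-rate series
#'
#' An `hr_series` is a tibble with one row per heart-rate sample: `t_sec`
#' (seconds since stream start, strictly increasing), `hr_bpm` (instantaneous
#' heart rate in beats per minute as reported by the device) and `valid`
#' (FALSE for physiologically implausible samples, which are kept but ignored
#' by downstream beat counting). The nominal sampling rate (default 1 Hz) is
#' stored as an attribute and supplies the duration of the final sample.
#'
#' Samples outside the plausible range (25, 250) bpm are flagged invalid
#' rather than dropped, so gaps and artefacts stay visible. Recording gaps
#' are never interpolated; see [hr_gaps()] and [count_mbeats()].
#'
#' @param t_sec Numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param hr_bpm Numeric vector of heart rates, same length as `t_sec`.
#' @param nominal_rate Nominal sampling rate in samples per second.
#' @return A tibble of class `hr_series` with columns `t_sec`, `hr_bpm`,
#'   `valid`.
#' @examples
#' hr_series(0:9, rep(120, 10))
#' @export
hr_series <- function(t_sec, hr_bpm, nominal_rate = 1) {
  cf_assert(is.numeric(t_sec) && is.numeric(hr_bpm),
            "`t_sec` and `hr_bpm` must be numeric.")
  cf_assert(length(t_sec) == length(hr_bpm),
            "`t_sec` and `hr_bpm` must have the same length.")
  cf_assert(is_number(nominal_rate) && nominal_rate > 0,
            "`nominal_rate` must be a positive number.")
  if (length(t_sec) > 1 && any(diff(t_sec) <= 0)) {
    bad <- which(diff(t_sec) <= 0)[1] + 1L
    cf_abort(sprintf(
      "Timestamps must be strictly increasing (violated at sample %d, t = %g).",
      bad, t_sec[bad]))
  }
  out <- tibble(
    t_sec = as.double(t_sec),
    hr_bpm = as.double(hr_bpm),
    valid = is.finite(hr_bpm) & hr_bpm > 25 & hr_bpm < 250
  )
  structure(out, nominal_rate = nominal_rate,
            class = c("hr_series", class(out)))
}

#' Nominal sampling rate of a heart-rate series
#' @param series An [hr_series()].
#' @return Samples per second.
#' @export
nominal_rate <- function(series) {
  attr(series, "nominal_rate") %||% 1
}

# Per-sample durations: left-value accounting, Delta-t from the next sample,
# with the final sample getting one nominal sample period.
sample_dt <- function(series) {
  n <- nrow(series)
  if (n == 0) return(numeric(0))
  c(diff(series$t_sec), 1 / nominal_rate(series))
}

#' Locate recording gaps in a heart-rate series
#'
#' A gap is an inter-sample interval longer than `gap_threshold` seconds.
#' Gaps are reported, never interpolated: beat counting assigns zero beats
#' to the gapped interval.
#'
#' @param series An [hr_series()].
#' @param gap_threshold Seconds; intervals longer than this are gaps.
#' @return Tibble with columns `start_s`, `end_s`, `dt_s`, one row per gap.
#' @export
hr_gaps <- function(series, gap_threshold = 5) {
  validate_hr_series(series)
  dt <- diff(series$t_sec)
  idx <- which(dt > gap_threshold)
  tibble(start_s = series$t_sec[idx], end_s = series$t_sec[idx + 1L],
         dt_s = dt[idx])
}

validate_hr_series <- function(series) {
  cf_assert(inherits(series, "hr_series") ||
              (is.data.frame(series) && all(c("t_sec", "hr_bpm") %in% names(series))),
            "Expected an `hr_series` (or data frame with `t_sec`, `hr_bpm`).")
  if (!inherits(series, "hr_series")) {
    series <- hr_series(series$t_sec, series$hr_bpm)
  } else if (nrow(series) > 1 && any(diff(series$t_sec) <= 0)) {
    cf_abort("Timestamps must be strictly increasing.")
  }
  invisible(series)
}

#' Read a heart-rate stream from CSV
#'
#' Expects the two-column dialect `t_sec,hr_bpm`. Malformed cells and
#' ordering violations are reported with their line numbers (header = line 1).
#'
#' @param path Path to a CSV file with header `t_sec,hr_bpm`.
#' @param nominal_rate Nominal sampling rate in samples per second.
#' @return An [hr_series()].
#' @export
read_hr_csv <- function(path, nominal_rate = 1) {
  cf_assert(file.exists(path), sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!identical(names(raw)[1:2], c("t_sec", "hr_bpm")) || ncol(raw) < 2) {
    cf_abort(sprintf("%s: expected header `t_sec,hr_bpm`, found `%s`.",
                     path, paste(names(raw), collapse = ",")))
  }
  t_sec <- suppressWarnings(as.double(raw$t_sec))
  hr_bpm <- suppressWarnings(as.double(raw$hr_bpm))
  bad <- which(!is.finite(t_sec) | is.na(hr_bpm))
  if (length(bad)) {
    cf_abort(sprintf("%s: non-numeric cells on line(s) %s.",
                     path, paste(bad + 1L, collapse = ", ")))
  }
  if (length(t_sec) > 1 && any(diff(t_sec) <= 0)) {
    bad <- which(diff(t_sec) <= 0)[1] + 1L
    cf_abort(sprintf("%s: timestamps not strictly increasing at line %d.",
                     path, bad + 1L))
  }
  hr_series(t_sec, hr_bpm, nominal_rate = nominal_rate)
}

#' Write a heart-rate stream to CSV
#'
#' Inverse of [read_hr_csv()]; writing then reading reproduces the series
#' exactly (full-precision doubles).
#'
#' @param series An [hr_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hr_csv <- function(series, path) {
  validate_hr_series(series)
  readr::write_csv(series[, c("t_sec", "hr_bpm")], path, progress = FALSE)
  invisible(path)
}

#' Plot a heart-rate series
#'
#' Line plot of heart rate over time; invalid samples are marked, and an
#' optional target zone is drawn as a shaded band.
#'
#' @param object An [hr_series()].
#' @param zone Optional [hr_zone()] to shade.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hr_series <- function(object, zone = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$t_sec, y = .data$hr_bpm))
  if (!is.null(zone)) {
    p <- p + ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                               ymin = zone$lower, ymax = zone$upper,
                               alpha = 0.15, fill = "forestgreen")
  }
  p +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_point(data = dplyr::filter(object, !.data$valid),
                        shape = 4, colour = "grey40") +
    ggplot2::labs(x = "Time (s)", y = "Heart rate (bpm)") +
    ggplot2::theme_minimal()
}
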