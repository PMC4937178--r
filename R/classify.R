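#' Load a fitness-classification table
#'
#' A classification table assigns an ordered fitness category (lowest to
#' highest) to an estimated VO2max within a sex-by-age stratum. The package
#' ships a synthetic editable default (`inst/extdata/classes.yaml`); the
#' published ACSM norm values are not redistributed.
#'
#' @param path Path to a YAML table; `NULL` loads the shipped default.
#' @return A list of class `class_table` with elements `source_table`,
#'   `categories` (ordered character vector) and `bands` (tibble with
#'   `sex`, `age_min`, `age_max` and a list-column `cutpoints`).
#' @export
read_class_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "classes.yaml", package = "cardiofit")
  cf_assert(nzchar(path) && file.exists(path), sprintf("File not found: %s", path))
  cfg <- yaml::read_yaml(path)
  cf_assert(all(c("source_table", "categories", "bands") %in% names(cfg)),
            "Classification table needs `source_table`, `categories`, `bands`.")
  k <- length(cfg$categories)
  cf_assert(k >= 2, "Need at least two fitness categories.")
  bands <- purrr::imap_dfr(cfg$bands, function(rows, sex) {
    purrr::map_dfr(rows, function(b) {
      cf_assert(length(b$cutpoints) == k - 1,
                sprintf("Each band needs %d cutpoints for %d categories.", k - 1, k))
      cf_assert(!is.unsorted(b$cutpoints, strictly = TRUE),
                "Cutpoints must be strictly increasing.")
      tibble(sex = normalize_sex(sex), age_min = b$age_min, age_max = b$age_max,
             cutpoints = list(as.double(b$cutpoints)))
    })
  })
  structure(list(source_table = cfg$source_table,
                 categories = as.character(cfg$categories), bands = bands),
            class = "class_table")
}

#' Classify a participant's fitness
#'
#' Deterministic lookup of the ordered fitness category for a profile's
#' estimated VO2max in its sex-by-age stratum. Values below the stratum's
#' lowest cutpoint clamp to the lowest category; values at or above the
#' highest cutpoint take the highest.
#'
#' @param profile A [participant_profile()] with `vo2max` set.
#' @param table A `class_table` from [read_class_table()]; default table if
#'   omitted.
#' @return A one-row tibble with `category` (ordered factor over the table's
#'   categories) and `source_table`.
#' @examples
#' p <- participant_profile(age = 45, sex = "female", hr_rest = 68, vo2max = 26.9)
#' classify_fitness(p)
#' @export
classify_fitness <- function(profile, table = read_class_table()) {
  cf_assert(inherits(table, "class_table"), "`table` must be a class_table.")
  cf_assert(is.data.frame(profile) && nrow(profile) == 1L,
            "`profile` must be a single participant profile row.")
  if (!is.finite(profile$vo2max)) {
    cf_abort("Profile has no `vo2max` estimate; run a fitness test first.")
  }
  hit <- dplyr::filter(table$bands, .data$sex == profile$sex,
                       .data$age_min <= profile$age, profile$age <= .data$age_max)
  if (nrow(hit) == 0) {
    cf_abort(sprintf("No classification band covers sex=%s, age=%g.",
                     profile$sex, profile$age))
  }
  cuts <- hit$cutpoints[[1]]
  idx <- findInterval(profile$vo2max, cuts) + 1L
  tibble(category = factor(table$categories[idx], levels = table$categories,
                           ordered = TRUE),
         source_table = table$source_table)
}

#' Load a FITT prescription table
#'
#' Maps each fitness category to admissible ranges of intensity (fraction of
#' heart-rate reserve), session duration (minutes) and weekly frequency.
#'
#' @param path Path to a YAML table; `NULL` loads the shipped default.
#' @return A tibble of class `fitt_table` with columns `category`,
#'   `intensity_min`, `intensity_max`, `duration_min`, `duration_max`,
#'   `frequency_min`, `frequency_max`.
#' @export
read_fitt_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "fitt.yaml", package = "cardiofit")
  cf_assert(nzchar(path) && file.exists(path), sprintf("File not found: %s", path))
  cfg <- yaml::read_yaml(path)
  out <- purrr::imap_dfr(cfg, function(row, category) {
    cf_assert(all(c("intensity", "duration_min", "frequency") %in% names(row)),
              sprintf("FITT entry `%s` needs intensity, duration_min, frequency.",
                      category))
    tibble(category = category,
           intensity_min = row$intensity[[1]], intensity_max = row$intensity[[2]],
           duration_min = row$duration_min[[1]], duration_max = row$duration_min[[2]],
           frequency_min = row$frequency[[1]], frequency_max = row$frequency[[2]])
  })
  cf_assert(all(out$intensity_min > 0 & out$intensity_max < 1),
            "FITT intensities must lie in (0, 1).")
  structure(out, class = c("fitt_table", class(out)))
}
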