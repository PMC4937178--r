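#' Create a participant profile
#'
#' Demographics and resting physiology used by the prescription engine and
#' the submaximal fitness tests. Maximal heart rate defaults to the
#' age-predicted `220 - age`; a measured maximum can be supplied via
#' `hr_max` to override it.
#'
#' @param age Age in whole years, in (0, 120).
#' @param sex `"female"` or `"male"` (or `"F"`/`"M"`).
#' @param hr_rest Resting heart rate, bpm; must be below `hr_max`.
#' @param height_m Height in meters (optional).
#' @param weight_kg Weight in kilograms (optional).
#' @param vo2max Estimated maximal oxygen uptake, mL/kg/min (optional at
#'   creation; required for fitness classification).
#' @param hr_max Measured maximal heart rate, bpm; defaults to `220 - age`.
#' @param id Participant identifier.
#' @return A one-row tibble of class `participant_profile` with columns
#'   `id`, `age`, `sex`, `height_m`, `weight_kg`, `hr_rest`, `hr_max`,
#'   `vo2max`.
#' @examples
#' participant_profile(age = 45, sex = "female", hr_rest = 68, vo2max = 26.9)
#' @export
participant_profile <- function(age, sex, hr_rest, height_m = NA_real_,
                                weight_kg = NA_real_, vo2max = NA_real_,
                                hr_max = NULL, id = "P01") {
  sex <- normalize_sex(sex)
  hr_max <- hr_max %||% estimate_hr_max(age)
  cf_assert(is_number(hr_max) && hr_max > 0, "`hr_max` must be positive.")
  cf_assert(is_number(hr_rest) && hr_rest > 0 && hr_rest < hr_max,
            "`hr_rest` must satisfy 0 < hr_rest < hr_max.")
  out <- tibble(id = as.character(id), age = as.double(age), sex = sex,
                height_m = as.double(height_m), weight_kg = as.double(weight_kg),
                hr_rest = as.double(hr_rest), hr_max = as.double(hr_max),
                vo2max = as.double(vo2max))
  structure(out, class = c("participant_profile", class(out)))
}

normalize_sex <- function(sex) {
  cf_assert(is.character(sex) && length(sex) == 1L, "`sex` must be a string.")
  key <- c(female = "female", f = "female", male = "male", m = "male")
  val <- key[tolower(sex)]
  if (is.na(val)) cf_abort(sprintf("Unknown sex `%s`; use female/male.", sex))
  unname(val)
}

#' Age-predicted maximal heart rate
#'
#' The classic age-predicted maximum, `220 - age`.
#'
#' @param age Age in years; rejected outside (0, 120).
#' @return Estimated maximal heart rate in bpm.
#' @examples
#' estimate_hr_max(40) # 180
#' @export
estimate_hr_max <- function(age) {
  cf_assert(is.numeric(age) && length(age) >= 1L && all(is.finite(age)),
            "`age` must be numeric.")
  if (any(age <= 0 | age >= 120)) {
    cf_abort("`age` must lie strictly between 0 and 120 years.")
  }
  220 - age
}

#' Karvonen (heart-rate-reserve) target heart rate
#'
#' Target HR = (HRmax - HRrest) x intensity + HRrest, where the intensity is
#' a fraction of the heart-rate reserve (HRR). Strictly increasing in the
#' intensity fraction, with limits HRrest (intensity -> 0) and HRmax
#' (intensity -> 1).
#'
#' @param hr_max Maximal heart rate, bpm.
#' @param hr_rest Resting heart rate, bpm; must be below `hr_max`.
#' @param intensity_fraction Desired intensity as a fraction of HRR, in (0, 1).
#' @return Target heart rate in bpm (real-valued; round only for display).
#' @examples
#' karvonen_target_hr(190, 90, 0.30) # 120
#' @export
karvonen_target_hr <- function(hr_max, hr_rest, intensity_fraction) {
  cf_assert(is.numeric(hr_max) && is.numeric(hr_rest) &&
              is.numeric(intensity_fraction),
            "All arguments must be numeric.")
  if (any(hr_rest >= hr_max)) {
    cf_abort("`hr_rest` must be strictly below `hr_max`.")
  }
  if (any(intensity_fraction <= 0 | intensity_fraction >= 1)) {
    cf_abort("`intensity_fraction` must lie strictly inside (0, 1).")
  }
  (hr_max - hr_rest) * intensity_fraction + hr_rest
}

#' Read participant profiles from CSV
#'
#' Expects the header `id,age,sex,height_m,weight_kg,hr_rest,vo2max`
#' with sex coded `F`/`M`.
#'
#' @param path Path to the CSV file.
#' @return A tibble with one validated profile per row.
#' @export
read_profiles_csv <- function(path) {
  cf_assert(file.exists(path), sprintf("File not found: %s", path))
  want <- c("id", "age", "sex", "height_m", "weight_kg", "hr_rest", "vo2max")
  raw <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(), sex = readr::col_character(),
    .default = readr::col_double()), progress = FALSE)
  missing <- setdiff(want, names(raw))
  if (length(missing)) {
    cf_abort(sprintf("%s: missing column(s) %s.", path,
                     paste(missing, collapse = ", ")))
  }
  purrr::pmap_dfr(raw[want], function(id, age, sex, height_m, weight_kg,
                                      hr_rest, vo2max) {
    participant_profile(age = age, sex = sex, hr_rest = hr_rest,
                        height_m = height_m, weight_kg = weight_kg,
                        vo2max = vo2max, id = id)
  })
}
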