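# Synthetic heart-rate and cohort generators. All generators are pure
# functions of (parameters, seed): the same call is bit-reproducible, and a
# single user seed fans out to per-component substreams.
#
# The response model is first-order (mono-exponential) on/off kinetics: HR
# relaxes toward the exercise target with time constant `onset_tau` and back
# toward rest with `recovery_tau`, plus additive Gaussian measurement noise.
# This is a deliberately simple, synthetic-only model; it is not fitted to
# any recorded data.

#' Create a simulation persona
#'
#' Parameter bundle for the synthetic generators. The recovery and onset
#' time constants shrink with `fitness` (fitter hearts respond and recover
#' faster), and the latent "true" VO2max grows with it, spanning roughly the
#' 20-45 mL/kg/min range of a sedentary-to-average adult cohort.
#'
#' @param age Years.
#' @param sex `"female"` or `"male"`.
#' @param hr_rest Resting HR, bpm.
#' @param fitness Dimensionless fitness level in `[0, 1]`.
#' @param hr_max Maximal HR, bpm; default `220 - age`.
#' @param onset_tau,recovery_tau Exercise-onset / recovery time constants in
#'   seconds; defaults decrease linearly in `fitness`.
#' @param noise_sd Measurement noise SD, bpm.
#' @param daily_steps_mean,daily_steps_sd Free-living daily step count mean
#'   and SD.
#' @param vo2max_true Latent true VO2max, mL/kg/min; default
#'   `20 + 25 fitness`.
#' @return A one-row tibble of class `persona`.
#' @examples
#' persona(fitness = 0.8)
#' @export
persona <- function(age = 40, sex = "female", hr_rest = 70, fitness = 0.5,
                    hr_max = NULL, onset_tau = NULL, recovery_tau = NULL,
                    noise_sd = 2, daily_steps_mean = 7500,
                    daily_steps_sd = 3000, vo2max_true = NULL) {
  cf_assert(is_number(fitness) && fitness >= 0 && fitness <= 1,
            "`fitness` must lie in [0, 1].")
  hr_max <- hr_max %||% estimate_hr_max(age)
  onset_tau <- onset_tau %||% (45 - 20 * fitness)
  recovery_tau <- recovery_tau %||% (70 - 40 * fitness)
  vo2max_true <- vo2max_true %||% (20 + 25 * fitness)
  cf_assert(is_number(hr_rest) && hr_rest > 0 && hr_rest < hr_max,
            "`hr_rest` must satisfy 0 < hr_rest < hr_max.")
  cf_assert(onset_tau > 0 && recovery_tau > 0, "Time constants must be positive.")
  cf_assert(is_number(noise_sd) && noise_sd >= 0, "`noise_sd` must be >= 0.")
  out <- tibble(age = as.double(age), sex = normalize_sex(sex),
                hr_rest = as.double(hr_rest), hr_max = as.double(hr_max),
                fitness = as.double(fitness), onset_tau = as.double(onset_tau),
                recovery_tau = as.double(recovery_tau),
                noise_sd = as.double(noise_sd),
                daily_steps_mean = as.double(daily_steps_mean),
                daily_steps_sd = as.double(daily_steps_sd),
                vo2max_true = as.double(vo2max_true))
  structure(out, class = c("persona", class(out)))
}

# Mono-exponential approach from `from` toward `to`, sampled at times t (s).
relax_toward <- function(t, from, to, tau) {
  if (tau < 1e-9) return(rep(to, length(t)))
  to - (to - from) * exp(-t / tau)
}

new_session <- function(clean, noisy, truth, seed) {
  structure(list(series = noisy, clean = clean, truth = truth,
                 seed = as.integer(seed)),
            class = "simulated_session")
}

#' @export
print.simulated_session <- function(x, ...) {
  cat(sprintf("<simulated_session> %d samples, seed %d\n",
              nrow(x$series), x$seed))
  print(x$truth)
  invisible(x)
}

#' Simulate a training bout
#'
#' A 1 Hz HR trace: `duration_s` of exercise relaxing from rest toward the
#' Karvonen target for `intensity_fraction`, followed by `recovery_s` of
#' exponential recovery, with additive Gaussian noise. Ground truth (beats
#' inside the zone) is computed on the noise-free trace.
#'
#' @param persona A [persona()].
#' @param intensity_fraction Fraction of heart-rate reserve, in (0, 1).
#' @param duration_s Exercise duration, seconds.
#' @param seed Integer seed; same seed, same trace.
#' @param recovery_s Recovery tail appended after exercise, seconds.
#' @param zone [hr_zone()] used for ground-truth beat counting; defaults to
#'   [zone_around()] the bout's target HR.
#' @param noise_sd Override the persona's noise SD (bpm).
#' @param onset_tau Override the persona's onset time constant (s); 0 gives
#'   an instantaneous step to target.
#' @return A `simulated_session`: list with the noisy `series`, the
#'   noise-free `clean` trace, a `truth` tibble (`target_hr`, `zone_lower`,
#'   `zone_upper`, `mbeats`) and the `seed`.
#' @export
simulate_bout <- function(persona, intensity_fraction, duration_s, seed,
                          recovery_s = 120, zone = NULL, noise_sd = NULL,
                          onset_tau = NULL) {
  cf_assert(inherits(persona, "persona"), "`persona` must be a persona().")
  cf_assert(is_number(duration_s) && duration_s >= 1,
            "`duration_s` must be at least 1 second.")
  cf_assert(is_number(recovery_s) && recovery_s >= 0,
            "`recovery_s` must be non-negative.")
  target <- karvonen_target_hr(persona$hr_max, persona$hr_rest,
                               intensity_fraction)
  zone <- zone %||% zone_around(target)
  noise_sd <- noise_sd %||% persona$noise_sd
  onset_tau <- onset_tau %||% persona$onset_tau
  t_ex <- seq_len(duration_s) - 1
  hr_ex <- relax_toward(t_ex, persona$hr_rest, target, onset_tau)
  hr_end <- hr_ex[length(hr_ex)]
  t_rec <- seq_len(recovery_s) - 1
  hr_rec <- relax_toward(t_rec, hr_end, persona$hr_rest, persona$recovery_tau)
  hr_clean <- c(hr_ex, hr_rec)
  t_all <- seq_along(hr_clean) - 1
  clean <- hr_series(t_all, hr_clean)
  noisy <- with_seed(substream_seed(seed, "bout"), {
    hr_series(t_all, hr_clean + rnorm(length(hr_clean), 0, noise_sd))
  })
  truth <- tibble(target_hr = target, zone_lower = zone$lower,
                  zone_upper = zone$upper, mbeats = count_mbeats(clean, zone))
  new_session(clean, noisy, truth, seed)
}

#' Simulate a squat test session
#'
#' Protocol timing: 180 s of seated rest, 45 s of paced squatting (HR rises
#' toward a peak that is higher for less fit personas), then 180 s of
#' recovery decaying with the persona's `recovery_tau`. Ground-truth
#' (P0, P1, P2) and the recovery index are read off the noise-free traces
#' with the same windows the scorer uses, so at zero noise the round trip is
#' exact.
#'
#' @param persona A [persona()].
#' @param seed Integer seed.
#' @param noise_sd Override the persona's noise SD (bpm).
#' @return A list of class `simulated_squat_test`: noisy `rest` and
#'   `recovery` traces, their `rest_clean`/`recovery_clean` counterparts, a
#'   `truth` tibble (`p0`, `p1`, `p2`, `rdi`) and the `seed`.
#' @export
simulate_squat_test <- function(persona, seed, noise_sd = NULL) {
  cf_assert(inherits(persona, "persona"), "`persona` must be a persona().")
  noise_sd <- noise_sd %||% persona$noise_sd
  peak <- persona$hr_rest +
    (persona$hr_max - persona$hr_rest) * (0.9 - 0.35 * persona$fitness)
  t_rest <- 0:179
  hr_rest_clean <- rep(persona$hr_rest, length(t_rest))
  t_ex <- 0:44
  hr_ex <- relax_toward(t_ex, persona$hr_rest, peak, 15)
  hr_end <- hr_ex[length(hr_ex)]
  t_rec <- 0:179
  hr_rec_clean <- relax_toward(t_rec, hr_end, persona$hr_rest,
                               persona$recovery_tau)
  rest_clean <- hr_series(t_rest, hr_rest_clean)
  recovery_clean <- hr_series(t_rec, hr_rec_clean)
  truth <- squat_test(rest_clean, recovery_clean)
  noisy <- with_seed(substream_seed(seed, "squat"), {
    list(rest = hr_series(t_rest, hr_rest_clean +
                            rnorm(length(t_rest), 0, noise_sd)),
         recovery = hr_series(t_rec, hr_rec_clean +
                                rnorm(length(t_rec), 0, noise_sd)))
  })
  structure(list(rest = noisy$rest, recovery = noisy$recovery,
                 rest_clean = rest_clean, recovery_clean = recovery_clean,
                 truth = as_tibble(truth), seed = as.integer(seed)),
            class = "simulated_squat_test")
}

#' Simulate a treadmill walk test session
#'
#' A 4-minute flat walk whose steady HR sits at 60% of the age-predicted
#' maximum (inside the protocol's 50-75% window), then a 5%-incline stage
#' at the same speed eliciting a modest HR rise, 4 minutes long.
#'
#' @param persona A [persona()].
#' @param speed_mph Belt speed, mph.
#' @param seed Integer seed.
#' @param noise_sd Override the persona's noise SD (bpm).
#' @return A `simulated_session`; `truth` holds the steady-state stage HR
#'   and the VO2max implied by the walk equation at that HR.
#' @export
simulate_treadmill_test <- function(persona, speed_mph = 3.4, seed,
                                    noise_sd = NULL) {
  cf_assert(inherits(persona, "persona"), "`persona` must be a persona().")
  noise_sd <- noise_sd %||% persona$noise_sd
  hr_pred_max <- estimate_hr_max(persona$age)
  walk_hr <- 0.60 * hr_pred_max
  stage_hr <- walk_hr + 14 - 6 * persona$fitness
  t_walk <- 0:239
  hr_walk <- relax_toward(t_walk, persona$hr_rest, walk_hr, persona$onset_tau)
  t_stage <- 0:239
  hr_stage <- relax_toward(t_stage, hr_walk[length(hr_walk)], stage_hr,
                           persona$onset_tau)
  hr_clean <- c(hr_walk, hr_stage)
  t_all <- seq_along(hr_clean) - 1
  clean <- hr_series(t_all, hr_clean)
  noisy <- with_seed(substream_seed(seed, "treadmill"), {
    hr_series(t_all, hr_clean + rnorm(length(hr_clean), 0, noise_sd))
  })
  truth <- tibble(speed = speed_mph, stage_hr = stage_hr,
                  vo2max = ebbeling_vo2max(speed_mph, stage_hr, persona$age,
                                           persona$sex))
  new_session(clean, noisy, truth, seed)
}

#' Simulate free-living daily step counts
#'
#' Lognormal draws matched to the persona's step mean and SD (free-living
#' step counts are right-skewed).
#'
#' @param persona A [persona()].
#' @param n_days Number of days.
#' @param seed Integer seed.
#' @return Tibble with `day` and `steps`.
#' @export
simulate_steps <- function(persona, n_days, seed) {
  cf_assert(inherits(persona, "persona"), "`persona` must be a persona().")
  cf_assert(is_number(n_days) && n_days >= 1, "`n_days` must be >= 1.")
  m <- persona$daily_steps_mean
  s <- persona$daily_steps_sd
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  with_seed(substream_seed(seed, "steps"), {
    tibble(day = seq_len(n_days),
           steps = round(rlnorm(n_days, meanlog, sdlog)))
  })
}

#' Default per-outcome effect settings for cohort simulation
#'
#' Group baselines and pre-to-post shifts used by [simulate_cohort()]. The
#' defaults emulate a three-group sedentary-adult intervention: VO2max
#' baselines around 27-37 mL/kg/min with a uniform modest improvement
#' (~+1.6 mL/kg/min, about 5% of the grand mean), small drops in blood
#' pressure and in resting/peak/recovery heart rates.
#'
#' @param groups Group labels.
#' @return Tibble with columns `outcome`, `group`, `baseline`, `time_delta`,
#'   `sd_subject`, `sd_resid`.
#' @export
default_cohort_effects <- function(groups = c("Step-App", "CF-App", "Super-CF")) {
  cf_assert(length(groups) == 3, "Default effects are defined for 3 groups.")
  base <- tibble(
    outcome = rep(c("vo2max", "sbp", "dbp", "hr_rest", "hr_peak",
                    "hr_recovery"), each = 3),
    group = rep(groups, times = 6),
    baseline = c(36.8, 26.9, 31.7,    # vo2max, mL/kg/min
                 121, 124, 122,       # sbp, mm Hg
                 76, 78, 77,          # dbp, mm Hg
                 68, 72, 70,          # hr_rest, bpm
                 148, 155, 151,       # hr_peak, bpm
                 95, 99, 97),         # hr_recovery, bpm
    time_delta = rep(c(1.6, -2.6, -1.5, -2, -3, -4), each = 3),
    sd_subject = rep(c(5, 10, 8, 7, 9, 9), each = 3),
    sd_resid = rep(c(2, 5, 4, 3.5, 4.5, 4.5), each = 3)
  )
  base
}

#' Null effect settings (no time shift, equal group baselines)
#'
#' @param outcome Outcome name.
#' @param baseline Common baseline.
#' @param sd_subject,sd_resid Between-subject and residual SDs.
#' @param groups Group labels.
#' @return Same shape as [default_cohort_effects()].
#' @export
null_cohort_effects <- function(outcome = "vo2max", baseline = 30,
                                sd_subject = 5, sd_resid = 2,
                                groups = c("Step-App", "CF-App", "Super-CF")) {
  tibble(outcome = outcome, group = groups, baseline = baseline,
         time_delta = 0, sd_subject = sd_subject, sd_resid = sd_resid)
}

#' Simulate a pre/post intervention cohort
#'
#' Each subject gets a random intercept (SD `sd_subject`); each measurement
#' adds residual noise (SD `sd_resid`); the post value additionally shifts
#' by the group's `time_delta`. Output is a tidy long table ready for
#' [mixed_anova()].
#'
#' @param n_per_group Integer vector of group sizes, named with group labels
#'   (default: the 16/17/12 three-group design).
#' @param effects Effect table from [default_cohort_effects()] /
#'   [null_cohort_effects()] or of the same shape.
#' @param seed Integer seed.
#' @return Tibble `subject`, `group`, `time` (`pre`/`post`), `outcome`,
#'   `value`.
#' @export
simulate_cohort <- function(n_per_group = c("Step-App" = 16, "CF-App" = 17,
                                            "Super-CF" = 12),
                            effects = default_cohort_effects(), seed = 1) {
  cf_assert(is.numeric(n_per_group) && all(n_per_group >= 2),
            "Each group needs at least 2 subjects.")
  groups <- names(n_per_group) %||% paste0("G", seq_along(n_per_group))
  cf_assert(all(groups %in% effects$group),
            "Every group needs a row per outcome in `effects`.")
  subjects <- tibble(
    subject = sprintf("S%03d", seq_len(sum(n_per_group))),
    group = rep(groups, times = n_per_group)
  )
  with_seed(substream_seed(seed, "cohort"), {
    purrr::map_dfr(unique(effects$outcome), function(oc) {
      eff <- effects[effects$outcome == oc, ]
      eff <- eff[match(subjects$group, eff$group), ]
      b_subj <- rnorm(nrow(subjects), 0, eff$sd_subject)
      pre <- eff$baseline + b_subj + rnorm(nrow(subjects), 0, eff$sd_resid)
      post <- eff$baseline + eff$time_delta + b_subj +
        rnorm(nrow(subjects), 0, eff$sd_resid)
      tibble(subject = rep(subjects$subject, 2),
             group = rep(subjects$group, 2),
             time = rep(c("pre", "post"), each = nrow(subjects)),
             outcome = oc, value = c(pre, post))
    })
  })
}

#' Simulate weekly step-count means over three weeks
#'
#' A three-level within-subject factor (baseline week and two intervention
#' weeks) for exercising the sphericity-correction machinery. Default
#' per-group week means follow the qualitative pattern of a step-app /
#' HR-app / supervised three-arm study: supervised training raises steps
#' sharply after baseline, app arms more gently.
#'
#' @param n_per_group Named integer vector of group sizes.
#' @param week_means Matrix (groups x 3 weeks) of mean daily steps.
#' @param sd_subject,sd_resid Between-subject and residual SDs (steps).
#' @param seed Integer seed.
#' @return Tibble `subject`, `group`, `time` (`week0`..`week2`), `outcome`
#'   (`"steps"`), `value`.
#' @export
simulate_step_weeks <- function(n_per_group = c("Step-App" = 16, "CF-App" = 17,
                                                "Super-CF" = 12),
                                week_means = rbind(c(8512, 9438, 9246),
                                                   c(6808, 7534, 7775),
                                                   c(6479, 10005, 9763)),
                                sd_subject = 1500, sd_resid = 900, seed = 1) {
  cf_assert(nrow(week_means) == length(n_per_group) && ncol(week_means) == 3,
            "`week_means` must be groups x 3 weeks.")
  groups <- names(n_per_group) %||% paste0("G", seq_along(n_per_group))
  n <- sum(n_per_group)
  grp_idx <- rep(seq_along(groups), times = n_per_group)
  with_seed(substream_seed(seed, "cohort") + 1L, {
    b_subj <- rnorm(n, 0, sd_subject)
    purrr::map_dfr(1:3, function(w) {
      tibble(subject = sprintf("S%03d", seq_len(n)),
             group = groups[grp_idx],
             time = paste0("week", w - 1L),
             outcome = "steps",
             value = week_means[grp_idx, w] + b_subj + rnorm(n, 0, sd_resid))
    })
  })
}

#' Simulate a fitness panel linking recovery kinetics to aerobic capacity
#'
#' Draws `n` personas with fitness levels spread over `[0, 1]` (hence
#' recovery time constants decreasing and latent VO2max increasing in
#' fitness), runs a noisy squat test on each, and returns the per-subject
#' recovery index alongside the latent truth. Used to check that the
#' recovery index carries a negative association with aerobic capacity.
#'
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @param noise_sd Measurement noise for the squat traces, bpm.
#' @return Tibble `subject`, `fitness`, `vo2max_true`, `rdi`.
#' @export
simulate_fitness_panel <- function(n = 20, seed = 1, noise_sd = 2) {
  cf_assert(is_number(n) && n >= 3, "`n` must be at least 3.")
  base <- substream_seed(seed, "persona")
  fit <- with_seed(base, stats::runif(n, 0.05, 0.95))
  purrr::map_dfr(seq_len(n), function(i) {
    p <- persona(fitness = fit[i], noise_sd = noise_sd)
    st <- simulate_squat_test(p, seed = (base + i) %% 2147483629)
    res <- squat_test(st$rest, st$recovery)
    tibble(subject = sprintf("S%03d", i), fitness = fit[i],
           vo2max_true = p$vo2max_true, rdi = res$rdi)
  })
}
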