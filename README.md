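# cardiofit

Heart-rate-reserve exercise prescription, a beats-in-zone training-load
metric, submaximal fitness testing and the accompanying cohort statistics —
as a tidyverse-native R package. It is aimed at exercise physiologists and
digital-health engineers who prescribe aerobic training from wearable
heart-rate streams and need the full loop to be computable, testable and
reproducible without device data.

## What it computes

**Prescription.** Training intensity is a fraction *p* of the heart-rate
reserve; the Karvonen target is

```
HR_target = (HR_max − HR_rest) · p + HR_rest,     HR_max = 220 − age (default)
```

A participant's estimated VO₂max is classified into an ordered fitness band
(configurable YAML table) and mapped through a FITT table to intensity,
session-duration and weekly-frequency ranges, taking the minimum of each —
the conservative starting dose. The weekly training goal in **mBeats**
(beats inside the personalized zone) is exactly
`HR_target × session_minutes × sessions_per_week`.

**Tracking.** `count_mbeats()` accumulates `hr/60 · Δt` over samples inside
the zone (inclusive bounds, no interpolation across recording gaps).
Weekly targets redistribute adaptively: at each day's start, the remaining
weekly mBeats are split equally over the remaining training days; rest-day
beats count as bonus.

**Fitness tests.** The Ruffier–Dickson squat test
(`RDI = ((P1 − 70) + 2(P2 − P0)) / 10`, lower = fitter) scored from rest
and recovery heart-rate traces, and the Ebbeling single-stage treadmill
walk with its VO₂max regression
`15.1 + 21.8·S − 0.327·HR − 0.263·S·age + 0.00504·HR·age + 5.98·sex`.

**Simulation.** Personas with first-order HR on/off kinetics generate
second-by-second bouts, complete test sessions and pre/post cohorts with
known ground truth, so every consumer is testable offline.

**Statistics.** A split-plot (two-way mixed) ANOVA engine with
Greenhouse–Geisser / Huynh–Feldt sphericity corrections (GG when
ε < 0.75, HF otherwise), Tukey HSD post-hoc comparisons and Pearson
correlation, for tidy long tables `subject, group, time, outcome, value`.

## Worked example

```r
library(cardiofit)

profile <- participant_profile(age = 30, sex = "female", hr_rest = 90, vo2max = 25)
(rx <- prescribe(profile))
#> <exercise_prescription>
#>   participant : P01 (very_poor)
#>   intensity   : 30% of HRR
#>   target HR   : 120 bpm
#>   dose        : 30 min x 3 sessions/week
#>   weekly goal : 10800 mBeats
```

The lowest fitness band maps to 0.30 HRR / 30 min / 3 sessions a week;
with resting HR 90 and maximal HR 190 the Karvonen target is 120 bpm, and
the weekly goal is 120 × 30 × 3 = 10,800 mBeats.

```r
wk <- training_week(rx$weekly_mbeats_target, c("T","R","T","R","T","R","R"))
adaptive_daily_target(wk, 1)
#> [1] 3600

# a simulated 30-minute session at the target, with 2 bpm sensor noise
session <- simulate_bout(persona(hr_rest = 90, hr_max = 190), 0.30, 1800, seed = 42)
round(count_mbeats(session$series, zone_around(rx$target_hr)))
#> [1] 3563   # ground truth on the noise-free trace: 3556

# after banking 7000 mBeats on day one, the remainder splits over
# the two training days left
wk <- record_day(wk, 1, mbeats = 7000)
wk <- record_day(wk, 2, mbeats = 0)
adaptive_daily_target(wk, 3)
#> [1] 1900
```

The 3600 is the even split of 10,800 over three training days; the counted
session falls a little short of 3600 because heart rate needs a couple of
minutes to climb into the zone. After a 7000-beat day, (10,800 − 7000)/2 =
1900 per remaining training day.

```r
sq <- simulate_squat_test(persona(fitness = 0.3), seed = 7)
squat_test(sq$rest, sq$recovery)
#> # A tibble: 1 × 4
#>      p0    p1    p2   rdi
#>   <dbl> <dbl> <dbl> <dbl>
#> 1  70.6  155.  96.8  13.8

coh <- simulate_cohort(seed = 42)   # three groups, pre/post, six outcomes
tidy(mixed_anova(coh, outcome = "vo2max"))[, c("effect", "df1", "df2", "statistic", "p.value")]
#> # A tibble: 5 × 5
#>   effect          df1   df2 statistic  p.value
#> 1 group             2    42     7.90   0.00123
#> 2 error_between    42    NA    NA     NA
#> 3 time              1    42     3.65   0.0629
#> 4 group:time        2    42     0.338  0.715
#> 5 error_within     42    NA    NA     NA
```

An RDI of 13.8 is a slow recovery (a fit persona scores several points
lower); the ANOVA table shows the split-plot layout — group tested against
between-subject variation, time and group×time against the within-subject
residual. With only two time levels no sphericity correction applies; fit
`simulate_step_weeks()` for a three-level example where it does.

A command-line interface wraps the same functions
(`Rscript inst/cli/cardiofit.R prescribe|track|status|test|simulate|analyze …`);
see `cardiofit_main()`.

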