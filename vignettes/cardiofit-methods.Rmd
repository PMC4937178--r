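---
title: "Methods: heart-rate-reserve prescription, beats-in-zone load, and the mixed-ANOVA engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heart-rate-reserve prescription, beats-in-zone load, and the mixed-ANOVA engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiofit)
```

cardiofit implements the computational core of a heart-rate-guided training
program for sedentary adults: an ACSM-style prescription engine, a
beats-in-zone training-load metric with adaptive daily targets, two
submaximal fitness tests, a synthetic wearable-data simulator, and the
split-plot ANOVA machinery used to analyse pre/post intervention cohorts.
This vignette explains the models, the defaults and the design decisions;
every empirical claim here is one the package's own tests or the acceptance
script computes.

## Prescription: Karvonen targets and FITT minima

Training intensity is expressed as a fraction of the heart-rate reserve
(HRR), the gap between maximal and resting heart rate. The target heart
rate is

$$\mathrm{HR}_{target} = (\mathrm{HR}_{max} - \mathrm{HR}_{rest})\cdot
  p + \mathrm{HR}_{rest}, \qquad p \in (0, 1),$$

with $\mathrm{HR}_{max}$ defaulting to the age-predicted $220 -$ age (a
measured maximum can override it on the profile). The prescription engine
classifies a participant's estimated VO~2~max into an ordered fitness band
and maps the band through a FITT table to ranges of intensity, session
duration and weekly frequency, taking the **minimum of each range**
independently — the conservative starting dose for a previously sedentary
participant.

Two configuration tables drive this. Their published reference values are
copyright-bound, so the package ships *synthetic, editable* YAML defaults
(`inst/extdata/classes.yaml`, `inst/extdata/fitt.yaml`) whose shape — five
ordered bands per sex-by-decade stratum, progressive-overload FITT ranges —
follows standard practice. One anchor is fixed by design and regression
tested: the lowest band prescribes 0.30 HRR, 30 minutes, 3 sessions/week.
Which intensity fractions a given study would assign above the lowest band
is genuinely open; the defaults are a documented choice, not a reference
fact.

Target heart rates are kept real-valued end to end; rounding to whole bpm is
purely a display concern. This keeps the weekly target identity exact:

$$\text{weekly target (mBeats)} = \mathrm{HR}_{target}\ (\text{bpm}) \times
  \text{session minutes} \times \text{sessions/week},$$

e.g. $120 \times 30 \times 3 = 10{,}800$ for the canonical sedentary
example.

## mBeats: beats inside a personalized zone

The training-load metric counts heart beats accumulated while the heart
rate lies inside a personalized zone. Devices report bpm samples, not beat
events, so the count is a left-Riemann accumulation: sample $i$ with rate
$h_i$ bpm and duration $\Delta t_i$ seconds (the interval to the next
sample; one nominal sample period for the last) contributes
$h_i/60 \cdot \Delta t_i$ beats iff $L \le h_i \le U$. Choices worth
stating:

* **Zone width.** No numeric width is published for the zone; the default
  is $\mathrm{HR}_{target} \pm 10$ bpm, configurable in `zone_around()`.
  A zone much narrower than the device noise floor makes in-zone credit
  erratic; ±10 bpm is wide relative to the ~2 bpm noise of a chest strap.
* **Gaps.** Inter-sample intervals longer than 5 s are treated as recording
  gaps and credited zero beats. Interpolating across a dropout would invent
  beats; the conservative rule under-counts slightly instead.
* **Implausible samples** (outside 25–250 bpm) are flagged and skipped, not
  dropped, so artefacts remain visible in the data.
* In-zone counting is strict: beats just outside the zone earn nothing.

Weekly targets redistribute adaptively at day granularity. At the start of
day $d$: rest days get 0; a training day gets
$\max(\text{weekly} - \text{achieved so far}, 0) / k$ where $k$ is the
number of remaining training days including day $d$. Beats collected on a
rest day count fully toward the week (bonus) and shrink subsequent targets.
Recomputation happens at day start only — matching the day-granular
worked example (10,800 → 3600/day → after 7000 on day one, 1900/day) —
not continuously within a day. A rest day with target 0 reports 100% when
nothing was collected, with any collected beats shown separately as bonus.

## Submaximal fitness tests

**Squat test.** A 45-second paced (40 bends/min) squatting exercise between
a rest period and a 3-minute recovery. Three window statistics at 1 Hz,
half-open $[a, b)$:

* $P_0$: mean HR over the final 15 s of rest. The protocol specifies only
  "15-s mean resting HR"; the window is placed at the *end* of rest, the
  state closest to exercise onset.
* $P_1$: maximum HR over recovery seconds 0–15;
* $P_2$: mean HR over recovery seconds 60–75.

The recovery index is $\mathrm{RDI} = ((P_1 - 70) + 2(P_2 - P_0))/10$.
Lower is fitter. The printed form of this formula is ambiguous about the
divisor's scope; the package uses the standard Ruffier–Dickson reading in
which the whole sum is divided by 10 (the alternative reading is
inconsistent with the index's conventional 0–20 scale). RDI is linear in
$(P_0, P_1, P_2)$ with coefficients $(-0.2, +0.1, +0.2)$, asserted by
finite differences in the tests.

**Treadmill walk test.** A 4-minute flat walk at a speed keeping HR within
50–75% of $220 -$ age (closed interval), then 4–5 minutes at a 5% incline
at the same speed. Minute HRs are 60-s window means; if minutes 7 and 8
differ by more than 6 bpm the test extends one minute. "Not more than
6 bpm" is read as $\le 6$. VO~2~max follows the single-stage walk
regression

$$\dot V\mathrm{O}_{2max} = 15.1 + 21.8\,S - 0.327\,H - 0.263\,S\,A +
  0.00504\,H\,A + 5.98\,G$$

with speed $S$ in mph, stage heart rate $H$ in bpm, age $A$ in years and
$G = 0$ (female) / $1$ (male). Which HR stands in for $H$ is not pinned
down by the protocol (end value vs stage mean); the package uses the mean
of the final 60 s of the incline stage, the most noise-robust steady-state
summary, and keeps the window configurable via `incline_start_s`. Speed
stays in mph end to end; metric input goes through an explicit
`kmh_to_mph()` conversion rather than a silent unit guess.

## The synthetic generators

No wearable data ships with the package; every consumer is testable against
simulated streams with known ground truth.

* **Kinetics.** HR follows first-order (mono-exponential) on/off kinetics:
  toward the Karvonen target with time constant `onset_tau`, back toward
  rest with `recovery_tau`, plus additive Gaussian noise (default SD
  2 bpm, a realistic chest-strap figure). This is the simplest defensible
  response model; it is synthetic-only and not fitted to any recording.
* **Personas.** `fitness` $\in [0,1]$ drives the physiology:
  `recovery_tau` $= 70 - 40 f$ s and `onset_tau` $= 45 - 20 f$ s (spanning
  the 30–70 s range typical of post-exercise HR decay), squat peak HR
  $= \mathrm{HR}_{rest} + (0.9 - 0.35 f)\,\mathrm{HRR}$, latent true
  VO~2~max $= 20 + 25 f$ mL/kg/min — the 20–45 range of a sedentary-to-
  average adult cohort. These couplings make the recovery index decrease
  monotonically in fitness, so the sign of the RDI–VO~2~max association is
  a genuine emergent check, not hard-wired.
* **Cohorts.** `simulate_cohort()` draws per-subject random intercepts and
  residual noise around group baselines, with a group-specific pre-to-post
  shift. Default group sizes are 16/17/12 and default effect sizes emulate
  a modest training response (VO~2~max +1.6 mL/kg/min ≈ +5% of the grand
  baseline; small blood-pressure and HR reductions). `simulate_step_weeks()`
  adds a three-level within factor for exercising the sphericity machinery.
  Step counts are lognormal (right-skewed, as free-living counts are).
* **Reproducibility.** Every generator is a pure function of (parameters,
  seed); a single user seed fans out to per-component substreams so adding
  a generator never perturbs existing output, and the caller's RNG state is
  never touched.

What passing tests on these data do **not** show: real wearables exhibit
motion artefacts, beat-detection dropouts correlated with intensity,
circadian drift and day-to-day autocorrelation, none of which the
generators model. Synthetic closure (e.g. noisy beat counts within 2% of
truth) bounds algorithmic error, not device error.

## The statistics engine

`mixed_anova()` implements the split-plot decomposition for one
between-subject factor (group) and one within-subject factor (time): group
is tested against subjects-within-groups, time and group×time against the
time×subject residual. The implementation is the package's own sums-of-
squares code (validated in tests against an independent brute-force oracle
and against `aov()`/`anova.mlm()`); `pf()`, `ptukey()` supply the reference
distributions.

With $t > 2$ within levels, sphericity corrections follow the
threshold rule: Greenhouse–Geisser when $\hat\varepsilon_{GG} < 0.75$,
Huynh–Feldt otherwise, applied by deflating both degrees of freedom of the
within-subject F tests. $\hat\varepsilon_{GG}$ comes from the pooled
within-group covariance of the repeated measures via orthonormal contrasts;
for Huynh–Feldt the package uses the Lecoutre-corrected multi-group
formula

$$\tilde\varepsilon = \frac{(N - g + 1)(t-1)\hat\varepsilon_{GG} - 2}
  {(t-1)\left(N - g - (t-1)\hat\varepsilon_{GG}\right)},$$

capped at 1 when applied — the same form R's multivariate ANOVA machinery
uses, preferred over the older uncorrected numerator. With $t = 2$ (the
pre/post design) sphericity holds trivially and no correction is applied;
the three-level step-count analysis is where the epsilon machinery is
exercised and tested. A table with zero error variance (e.g. all values
identical) yields flagged `NA` statistics with a warning rather than a
spurious result.

`tukey_posthoc()` computes Tukey–Kramer studentized-range comparisons —
on subject means (averaged over time) against the subjects-within-groups
stratum for the group effect, or on raw values at one time level. Estimates
are reported first-minus-second group. The significance threshold is the
caller's business: the engine never gates post-hocs on a significant
omnibus test. Textbook degrees of freedom are always reported
($g-1$ and $N-g$ for three groups), even where published tables in this
literature occasionally print inconsistent df for between-group effects.

## Numerical and degenerate-input choices

* All windows are half-open $[a, b)$ at nominal 1 Hz; window coverage is
  validated and errors name the offending window.
* mBeats, targets and HRs are doubles throughout; the worked-example
  arithmetic ($10{,}800$, $3600$, $1900$) is therefore integer-exact.
* Weekly percent requires a positive weekly target; a week with no
  remaining training days and unmet target yields 0-targets plus a warning.
* Classification clamps below-scale VO~2~max values to the lowest band but
  refuses strata (sex × age) the table does not cover.

## Problem sizes

The heavier self-checks run at deliberately modest scale chosen to keep the
Monte-Carlo error small relative to the margins being asserted: 1000 null
cohort simulations at 12 subjects/group for the type-I error of the time
effect (binomial SE ≈ 0.7 points at $\alpha = 5\%$), 200 simulated
20-subject panels for the sign of the RDI–VO~2~max association, and 100
seeds for noisy beat-count closure.
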