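# Shared fixture builders. All fixtures are generated in code.

constant_series <- function(duration_s, hr, rate = 1) {
  t <- seq(0, duration_s - 1 / rate, by = 1 / rate)
  hr_series(t, rep(hr, length(t)), nominal_rate = rate)
}

# Piecewise-constant recovery trace: `hr` gives the level on each 1-s sample.
stepped_series <- function(hr) hr_series(seq_along(hr) - 1, hr)

# Hand-checkable 2 groups x 2 times split-plot fixture.
cohort_2x2 <- function() {
  tibble::tibble(
    subject = rep(c("s1", "s2", "s3", "s4"), each = 2),
    group = rep(c("A", "A", "B", "B"), each = 2),
    time = factor(rep(c("pre", "post"), 4), levels = c("pre", "post")),
    value = c(10, 14, 12, 18, 20, 22, 24, 26)
  )
}

# Independent split-plot sums-of-squares oracle: explicit loops over the
# raw observations, no shared code with the package implementation.
splitplot_oracle <- function(data) {
  data$subject <- as.character(data$subject)
  data$group <- as.character(data$group)
  data$time <- as.character(data$time)
  subjects <- unique(data$subject)
  groups <- unique(data$group)
  times <- unique(data$time)
  n <- length(subjects); g <- length(groups); t_n <- length(times)
  grand <- mean(data$value)
  val <- function(s, tm) data$value[data$subject == s & data$time == tm]
  grp_of <- function(s) data$group[data$subject == s][1]

  ss_total <- sum((data$value - grand)^2)
  ss_bs <- 0
  for (s in subjects) {
    ss_bs <- ss_bs + t_n * (mean(sapply(times, function(tm) val(s, tm))) - grand)^2
  }
  ss_group <- 0
  for (gr in groups) {
    v <- data$value[data$group == gr]
    ss_group <- ss_group + length(v) * (mean(v) - grand)^2
  }
  ss_time <- 0
  for (tm in times) {
    v <- data$value[data$time == tm]
    ss_time <- ss_time + length(v) * (mean(v) - grand)^2
  }
  ss_cells <- 0
  for (gr in groups) for (tm in times) {
    v <- data$value[data$group == gr & data$time == tm]
    ss_cells <- ss_cells + length(v) * (mean(v) - grand)^2
  }
  ss_int <- ss_cells - ss_group - ss_time
  ss_subj_within <- ss_bs - ss_group
  ss_err <- ss_total - ss_bs - ss_time - ss_int
  list(
    f_group = (ss_group / (g - 1)) / (ss_subj_within / (n - g)),
    f_time = (ss_time / (t_n - 1)) / (ss_err / ((n - g) * (t_n - 1))),
    f_int = (ss_int / ((g - 1) * (t_n - 1))) / (ss_err / ((n - g) * (t_n - 1))),
    ss = c(group = ss_group, subj = ss_subj_within, time = ss_time,
           int = ss_int, err = ss_err, total = ss_total)
  )
}

# Random balanced long cohort for invariance checks.
random_cohort <- function(seed, n_per_group = c(A = 5, B = 4, C = 6),
                          times = c("pre", "post")) {
  withr::with_seed(seed, {
    groups <- rep(names(n_per_group), n_per_group)
    n <- length(groups)
    tibble::tibble(
      subject = rep(sprintf("s%02d", seq_len(n)), times = length(times)),
      group = rep(groups, times = length(times)),
      time = factor(rep(times, each = n), levels = times),
      value = stats::rnorm(n * length(times), mean = 50, sd = 8)
    )
  })
}
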