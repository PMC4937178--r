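test_that("beats in zone match the bpm x time product for steady traces", {
  s <- constant_series(1800, 120)
  expect_equal(count_mbeats(s, hr_zone(110, 130)), 3600)
  # entirely below the zone -> nothing credited
  expect_equal(count_mbeats(constant_series(600, 95), hr_zone(110, 130)), 0)
  # empty series
  expect_equal(count_mbeats(hr_series(numeric(0), numeric(0)),
                            hr_zone(110, 130)), 0)
  # inclusive bounds
  expect_equal(count_mbeats(constant_series(60, 110), hr_zone(110, 130)), 110)
})

test_that("beat counting equals a per-sample brute-force sum", {
  withr::with_seed(21, {
    for (i in 1:10) {
      n <- sample(200:600, 1)
      hr <- runif(n, 60, 180)
      s <- hr_series(0:(n - 1), hr)
      z <- hr_zone(100, 150)
      manual <- 0
      for (k in seq_len(n)) {
        if (hr[k] >= 100 && hr[k] <= 150) manual <- manual + hr[k] / 60
      }
      expect_equal(count_mbeats(s, z), manual, tolerance = 1e-9)
    }
  })
})

test_that("beat counting is additive over disjoint segments and linear in time", {
  withr::with_seed(22, {
    hr <- runif(400, 90, 160)
    z <- hr_zone(100, 150)
    whole <- hr_series(0:399, hr)
    first <- hr_series(0:199, hr[1:200])
    second <- hr_series(200:399, hr[201:400])
    expect_equal(count_mbeats(whole, z),
                 count_mbeats(first, z) + count_mbeats(second, z),
                 tolerance = 1e-9)
    # doubling every sampling interval doubles the count
    stretched <- hr_series((0:399) * 2, hr, nominal_rate = 0.5)
    expect_equal(count_mbeats(stretched, z), 2 * count_mbeats(whole, z),
                 tolerance = 1e-9)
  })
})

test_that("recording gaps and invalid samples contribute zero beats", {
  # 10 samples, then a 60-s dropout, then 10 more
  t <- c(0:9, 70:79)
  s <- hr_series(t, rep(120, 20))
  z <- hr_zone(110, 130)
  # the sample before the gap is not credited for the 61-s interval
  expect_equal(count_mbeats(s, z), (9 + 10) * 2)
  expect_equal(nrow(hr_gaps(s)), 1)
  expect_equal(hr_gaps(s)$dt_s, 61)
  # implausible readings are flagged invalid and skipped
  s2 <- hr_series(0:9, c(rep(120, 8), 300, 10))
  expect_identical(s2$valid, c(rep(TRUE, 8), FALSE, FALSE))
  expect_equal(count_mbeats(s2, hr_zone(0.5, 400)), 8 * 2)
  expect_error(hr_series(c(0, 1, 1, 2), rep(100, 4)),
               class = "cardiofit_validation_error")
})

test_that("adaptive daily targets redistribute the remaining weekly load", {
  wk <- training_week(10800, c("T", "R", "T", "R", "T", "R", "R"))
  expect_equal(adaptive_daily_target(wk), 3600)       # 3 training days left
  expect_equal(adaptive_daily_target(wk, day = 2), 0) # rest day
  wk <- record_day(wk, 1, mbeats = 7000)
  wk <- record_day(wk, 2, mbeats = 0)
  expect_equal(adaptive_daily_target(wk), 1900)       # (10800-7000)/2
  wk <- record_day(wk, 3, mbeats = 1900)
  wk <- record_day(wk, 4, mbeats = 0)
  expect_equal(adaptive_daily_target(wk), 1900)
  # overachievement clamps to zero for the rest of the week
  wk2 <- training_week(10800, c("T", "R", "T", "R", "T", "R", "R"))
  wk2 <- record_day(wk2, 1, mbeats = 12000)
  wk2 <- record_day(wk2, 2, mbeats = 0)
  expect_equal(adaptive_daily_target(wk2), 0)
  # no training days left but target unmet -> 0 with a warning
  wk3 <- training_week(5000, c("T", rep("R", 6)))
  wk3 <- record_day(wk3, 1, mbeats = 100)
  expect_warning(tgt <- adaptive_daily_target(wk3, day = 5))
  expect_equal(tgt, 0)
})

test_that("rest-day beats count as bonus and shrink later targets", {
  wk <- training_week(9000, c("T", "R", "T", "R", "T", "R", "R"))
  wk <- record_day(wk, 1, mbeats = 3000)
  wk <- record_day(wk, 2, mbeats = 1000) # bonus on a rest day
  expect_equal(adaptive_daily_target(wk), (9000 - 4000) / 2)
  prog <- day_progress(wk)
  expect_equal(prog$bonus, c(0, 1000))
  expect_equal(prog$percent_of_target, c(100 * 3000 / 3000, 100))
})

test_that("planned remaining targets always cover the remaining weekly load", {
  withr::with_seed(31, {
    for (i in 1:20) {
      types <- sample(c("T", "R"), 7, replace = TRUE, prob = c(0.6, 0.4))
      if (!any(types == "T")) types[1] <- "T"
      wk <- training_week(10000, types)
      for (d in 1:7) {
        tgt <- suppressWarnings(adaptive_daily_target(wk, d))
        achieved_so_far <- sum(wk$days$achieved, na.rm = TRUE)
        remaining <- max(10000 - achieved_so_far, 0)
        k <- sum(types[d:7] == "T")
        if (types[d] == "T") {
          # equal split over remaining training days reconstructs the remainder
          expect_equal(tgt * k, remaining, tolerance = 1e-9)
        } else {
          expect_equal(tgt, 0)
        }
        wk <- record_day(wk, d, mbeats = runif(1, 0, 4000))
      }
      # a week where every day hits its start-of-day target lands exactly on goal
      wk2 <- training_week(10000, types)
      for (d in 1:7) {
        wk2 <- record_day(wk2, d,
                          mbeats = suppressWarnings(adaptive_daily_target(wk2, d)))
      }
      expect_equal(sum(wk2$days$achieved), 10000, tolerance = 1e-9)
      expect_equal(weekly_percent(wk2), 100, tolerance = 1e-9)
    }
  })
})

test_that("weekly percentage is achieved over target and may exceed 100", {
  wk <- training_week(10800, c("T", "R", "T", "R", "T", "R", "R"))
  for (d in 1:7) wk <- record_day(wk, d, mbeats = c(5400, 0, 0, 0, 0, 0, 0)[d])
  expect_equal(weekly_percent(wk), 50)
  wk2 <- training_week(10000, rep(c("T", "R"), c(4, 3)))
  for (d in 1:7) wk2 <- record_day(wk2, d, mbeats = 2843)
  expect_gt(weekly_percent(wk2), 100) # overshoot weeks are representable
  expect_equal(weekly_percent(wk2), 100 * 7 * 2843 / 10000)
})

test_that("days must be recorded in order and from valid input", {
  wk <- training_week(10800, c("T", "R", "T", "R", "T", "R", "R"))
  expect_error(record_day(wk, 3, mbeats = 100),
               class = "cardiofit_validation_error")
  wk <- record_day(wk, 1, series = hr_series(numeric(0), numeric(0)),
                   zone = hr_zone(110, 130))
  expect_equal(wk$days$achieved[1], 0)
  # counting from a series matches count_mbeats
  s <- constant_series(600, 120)
  wk <- record_day(wk, 2, series = s, zone = hr_zone(110, 130))
  expect_equal(wk$days$achieved[2], 1200)
})

test_that("week state round-trips through JSON", {
  wk <- training_week(10800, c("T", "R", "T", "R", "T", "R", "R"))
  wk <- record_day(wk, 1, mbeats = 7000.25)
  path <- withr::local_tempfile(fileext = ".json")
  write_week_state(wk, path)
  back <- read_week_state(path)
  expect_equal(back$weekly_target, wk$weekly_target)
  expect_identical(back$days$type, wk$days$type)
  expect_identical(back$days$achieved, wk$days$achieved)
  expect_identical(back$current_day, wk$current_day)
})
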