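test_that("split-plot F statistics match hand arithmetic on the 2x2 fixture", {
  fit <- mixed_anova(cohort_2x2())
  tab <- tidy(fit)
  # hand-computable decomposition: SS_group 180.5 on MS_subj 12.5, etc.
  expect_equal(tab$sumsq[tab$effect == "group"], 180.5)
  expect_equal(tab$meansq[tab$effect == "error_between"], 12.5)
  expect_equal(tab$statistic[tab$effect == "group"], 14.44)
  expect_equal(tab$statistic[tab$effect == "time"], 49)
  expect_equal(tab$statistic[tab$effect == "group:time"], 9)
  expect_equal(tab$df1, c(1, 2, 1, 1, 2))
  # two within levels: sphericity trivially holds, no correction
  expect_identical(fit$correction, "none")
  expect_equal(tab$p.value[tab$effect == "time"],
               pf(49, 1, 2, lower.tail = FALSE))
})

test_that("split-plot decomposition matches a brute-force oracle on random designs", {
  for (seed in c(101, 202, 303)) {
    d <- random_cohort(seed)
    fit <- mixed_anova(d)
    tab <- tidy(fit)
    oracle <- splitplot_oracle(d)
    expect_equal(tab$statistic[tab$effect == "group"], oracle$f_group,
                 tolerance = 1e-10)
    expect_equal(tab$statistic[tab$effect == "time"], oracle$f_time,
                 tolerance = 1e-10)
    expect_equal(tab$statistic[tab$effect == "group:time"], oracle$f_int,
                 tolerance = 1e-10)
    # the component sums of squares add up to the total
    expect_equal(sum(tab$sumsq), glance(fit)$ss_total, tolerance = 1e-8)
    expect_equal(glance(fit)$ss_total, oracle$ss[["total"]], tolerance = 1e-8)
  }
})

test_that("results are invariant to row order, subject labels and group labels", {
  d <- random_cohort(17)
  base <- tidy(mixed_anova(d))
  shuffled <- withr::with_seed(1, d[sample(nrow(d)), ])
  expect_equal(tidy(mixed_anova(shuffled))$statistic, base$statistic)
  relabeled <- dplyr::mutate(d, subject = paste0("X_", .data$subject))
  expect_equal(tidy(mixed_anova(relabeled))$statistic, base$statistic)
  swapped <- dplyr::mutate(d, group = dplyr::recode(.data$group, A = "B", B = "A"))
  expect_equal(glance(mixed_anova(swapped))$ss_total, glance(mixed_anova(d))$ss_total)
})

test_that("degenerate constant data is flagged rather than reported significant", {
  d <- cohort_2x2()
  d$value <- 7
  expect_warning(fit <- mixed_anova(d), "error variance")
  expect_true(all(is.na(tidy(fit)$statistic[c(1, 3, 4)])))
})

test_that("unbalanced tables fail loudly, naming the offending subjects", {
  d <- cohort_2x2()[-1, ] # s1 loses its pre measurement
  err <- tryCatch(mixed_anova(d), error = function(e) conditionMessage(e))
  expect_match(err, "s1")
  # subject assigned to two groups is also unbalanced
  d2 <- cohort_2x2()
  d2$group[2] <- "B"
  expect_error(mixed_anova(d2), class = "cardiofit_validation_error")
})

test_that("sphericity epsilons agree with the multivariate reference machinery", {
  withr::with_seed(42, {
    n <- 12
    y <- matrix(rnorm(3 * n), n, 3) %*%
      chol(matrix(c(1, .7, .2, .7, 1, .5, .2, .5, 1), 3))
    grp <- factor(rep(c("A", "B"), each = 6))
    y[grp == "B", ] <- y[grp == "B", ] + 1
  })
  mlmfit <- lm(y ~ grp)
  idata <- data.frame(time = factor(c("t1", "t2", "t3")))
  sph <- stats:::sphericity(stats::SSD(mlmfit), M = ~time, X = ~1,
                            idata = idata)
  d <- tibble::tibble(
    subject = rep(sprintf("s%02d", 1:12), 3),
    group = rep(grp, 3),
    time = factor(rep(c("t1", "t2", "t3"), each = 12)),
    value = c(y))
  fit <- mixed_anova(d)
  expect_equal(fit$epsilon_gg, sph$GG.eps, tolerance = 1e-10)
  expect_equal(fit$epsilon_hf, sph$HF.eps, tolerance = 1e-10)
})

test_that("the epsilon rule picks GG under strong violation, HF otherwise", {
  # strong sphericity violation: one time level far noisier than the rest
  make_data <- function(sds) {
    withr::with_seed(7, {
      n <- 16
      y <- cbind(rnorm(n, 0, sds[1]), rnorm(n, 0, sds[2]), rnorm(n, 0, sds[3]))
      tibble::tibble(
        subject = rep(sprintf("s%02d", 1:n), 3),
        group = rep(rep(c("A", "B"), each = n / 2), 3),
        time = factor(rep(c("t1", "t2", "t3"), each = n)),
        value = c(y))
    })
  }
  viol <- mixed_anova(make_data(c(1, 1, 25)))
  expect_lt(viol$epsilon_gg, 0.75)
  expect_identical(viol$correction, "GG")
  tab <- tidy(viol)
  t_row <- tab[tab$effect == "time", ]
  # corrected p uses epsilon-deflated dfs on the same F
  expect_equal(t_row$p.value,
               pf(t_row$statistic, viol$epsilon_gg * 2,
                  viol$epsilon_gg * 28, lower.tail = FALSE))
  ok <- mixed_anova(make_data(c(1, 1.1, 0.9)))
  expect_gt(ok$epsilon_gg, 0.75)
  expect_identical(ok$correction, "HF")
  # HF epsilon is capped at 1 when applied
  expect_lte(tidy(ok)$epsilon[3], 1)
})

test_that("Tukey HSD reduces to the paired t-family at k = 2 and is antisymmetric", {
  d <- random_cohort(23, n_per_group = c(A = 8, B = 8))
  tk <- tukey_posthoc(d)
  expect_equal(nrow(tk), 1)
  # reference route: one-way aov + TukeyHSD on the subject means
  subj <- dplyr::summarise(dplyr::group_by(d, subject, group),
                           value = mean(value), .groups = "drop")
  ref <- TukeyHSD(aov(value ~ group, data = subj))$group
  expect_equal(unname(tk$adj.p.value), unname(ref[, "p adj"]), tolerance = 1e-9)
  expect_equal(abs(tk$estimate), abs(ref[, "diff"]), tolerance = 1e-12,
               ignore_attr = TRUE)
  # with two groups the studentized-range p equals the two-sided t-test p
  tt <- t.test(value ~ group, data = subj, var.equal = TRUE)
  expect_equal(tk$adj.p.value, tt$p.value, tolerance = 1e-9)
  # antisymmetry: relabelling the groups flips the estimate's sign
  dd <- dplyr::mutate(d, group = dplyr::recode(group, A = "Z"))
  tk2 <- tukey_posthoc(dd)
  expect_equal(tk2$estimate, -tk$estimate, tolerance = 1e-12)
})

test_that("Tukey HSD matches the reference route with three unequal groups", {
  d <- random_cohort(29, n_per_group = c(A = 7, B = 5, C = 9))
  tk <- tukey_posthoc(d)
  subj <- dplyr::summarise(dplyr::group_by(d, subject, group),
                           value = mean(value), .groups = "drop")
  ref <- TukeyHSD(aov(value ~ group, data = subj))$group
  expect_equal(nrow(tk), 3)
  expect_equal(unname(tk$adj.p.value), unname(ref[, "p adj"]), tolerance = 1e-8)
  # TukeyHSD reports later-minus-earlier differences; ours are
  # first-minus-second, so the intervals are mirrored
  expect_equal(tk$conf.low, -ref[, "upr"], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(tk$conf.high, -ref[, "lwr"], tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(tukey_posthoc(dplyr::filter(d, group == "A")),
               class = "cardiofit_validation_error")
})

test_that("Tukey HSD controls the familywise error under equal means", {
  res <- vapply(1:300, function(s) {
    d <- random_cohort(1000 + s, n_per_group = c(A = 15, B = 15, C = 15))
    p <- tukey_posthoc(d)$adj.p.value
    c(any_rejection = any(p < 0.05), mean_p = mean(p))
  }, numeric(2))
  expect_lt(mean(res["any_rejection", ]), 0.08) # familywise alpha ~ 0.05
  expect_gt(mean(res["mean_p", ]), 0.5)         # null p-values sit high
})

test_that("comparisons at a single time level use the raw one-way layout", {
  d <- random_cohort(31)
  tk <- tukey_posthoc(d, effect = "group_at_time", at = "post")
  post <- dplyr::filter(d, time == "post")
  ref <- TukeyHSD(aov(value ~ group, data = post))$group
  expect_equal(unname(tk$adj.p.value), unname(ref[, "p adj"]), tolerance = 1e-8)
  expect_error(tukey_posthoc(d, effect = "group_at_time", at = "nope"),
               class = "cardiofit_validation_error")
})

test_that("Pearson correlation matches the product-moment formula", {
  expect_equal(pearson_r(1:10, 1:10 * 2 + 3)$estimate, 1)
  expect_equal(pearson_r(1:10, -(1:10))$estimate, -1)
  withr::with_seed(5, {
    x <- rnorm(40); y <- rnorm(40)
    r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(pearson_r(x, y)$estimate, r_oracle, tolerance = 1e-12)
  })
  expect_error(pearson_r(rep(1, 5), 1:5), class = "cardiofit_validation_error")
  expect_error(pearson_r(1:2, 1:2), class = "cardiofit_validation_error")
})
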