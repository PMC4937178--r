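#' Split-plot (two-way mixed) ANOVA
#'
#' One between-subject factor (`group`) crossed with one within-subject
#' factor (`time`), the classic design for pre/post intervention cohorts.
#' Sums of squares follow the standard split-plot decomposition: group is
#' tested against subjects-within-group, time and the group-by-time
#' interaction against the time-by-subject residual.
#'
#' With more than two within-subject levels, sphericity matters: the
#' Greenhouse-Geisser epsilon is computed from the pooled within-group
#' covariance of the repeated measures, and the within-subject F tests are
#' corrected by deflating their degrees of freedom — Greenhouse-Geisser when
#' epsilon < 0.75, Huynh-Feldt otherwise. With exactly two levels sphericity
#' holds trivially and no correction is applied.
#'
#' @param data Tidy long tibble with columns `subject`, `group`, `time`,
#'   `value` (and optionally `outcome`).
#' @param outcome If `data` has an `outcome` column, which outcome to
#'   analyse.
#' @param epsilon_threshold Epsilon below which the Greenhouse-Geisser
#'   rather than Huynh-Feldt correction is used (default 0.75).
#' @return An object of class `cf_anova`; see [tidy.cf_anova()] for the
#'   effect table. Each tested effect carries `statistic` (F), raw and
#'   corrected dfs, `epsilon`, the `correction` used and `p.value`.
#' @examples
#' coh <- simulate_cohort(c(A = 6, B = 6), null_cohort_effects(groups = c("A", "B")),
#'                        seed = 7)
#' mixed_anova(coh, outcome = "vo2max")
#' @export
mixed_anova <- function(data, outcome = NULL, epsilon_threshold = 0.75) {
  data <- prepare_cohort(data, outcome)
  times <- levels(data$time)
  t_n <- length(times)

  wide <- tidyr::pivot_wider(data, id_cols = c("subject", "group"),
                             names_from = "time", values_from = "value")
  y <- as.matrix(wide[, times])
  grp <- wide$group
  groups <- levels(grp)
  g <- length(groups)
  n_j <- as.vector(table(grp))
  n <- nrow(wide)
  cf_assert(all(n_j >= 2), "Each group needs at least 2 subjects.")

  grand <- mean(y)
  subj_means <- rowMeans(y)
  grp_means <- tapply(subj_means, grp, mean)
  time_means <- colMeans(y)
  cell_means <- rowsum(y, grp) / n_j  # g x t

  ss_total <- sum((y - grand)^2)
  ss_between_subj <- t_n * sum((subj_means - grand)^2)
  ss_group <- t_n * sum(n_j * (grp_means - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_time <- n * sum((time_means - grand)^2)
  ss_cells <- sum(n_j * (cell_means - grand)^2)
  ss_interaction <- ss_cells - ss_group - ss_time
  ss_error_within <- ss_total - ss_between_subj - ss_time - ss_interaction

  df_group <- g - 1
  df_subj <- n - g
  df_time <- t_n - 1
  df_int <- (g - 1) * (t_n - 1)
  df_err <- (n - g) * (t_n - 1)

  ms <- function(ss, df) if (df > 0) ss / df else NA_real_
  ms_subj <- ms(ss_subj_within, df_subj)
  ms_err <- ms(ss_error_within, df_err)
  degenerate <- FALSE
  f_of <- function(ss, df, ms_e) {
    if (!is.finite(ms_e) || ms_e <= 0) {
      degenerate <<- TRUE
      return(NA_real_)
    }
    (ss / df) / ms_e
  }
  f_group <- f_of(ss_group, df_group, ms_subj)
  f_time <- f_of(ss_time, df_time, ms_err)
  f_int <- f_of(ss_interaction, df_int, ms_err)
  if (degenerate) {
    rlang::warn("Zero error variance: F statistics undefined (flagged NA).")
  }

  if (t_n > 2) {
    eps <- sphericity_epsilons(y, grp, n_j)
    use_gg <- eps$gg < epsilon_threshold
    eps_used <- if (use_gg) eps$gg else min(eps$hf, 1)
    correction <- if (use_gg) "GG" else "HF"
  } else {
    eps <- list(gg = 1, hf = 1)
    eps_used <- 1
    correction <- "none"
  }

  p_between <- if (is.na(f_group)) NA_real_ else
    pf(f_group, df_group, df_subj, lower.tail = FALSE)
  p_within <- function(f, df1) {
    if (is.na(f)) return(NA_real_)
    pf(f, eps_used * df1, eps_used * df_err, lower.tail = FALSE)
  }

  table <- tibble(
    effect = c("group", "error_between", "time", "group:time", "error_within"),
    df1 = c(df_group, df_subj, df_time, df_int, df_err),
    df2 = c(df_subj, NA, df_err, df_err, NA),
    sumsq = c(ss_group, ss_subj_within, ss_time, ss_interaction,
              ss_error_within),
    meansq = c(ms(ss_group, df_group), ms_subj, ms(ss_time, df_time),
               ms(ss_interaction, df_int), ms_err),
    statistic = c(f_group, NA, f_time, f_int, NA),
    epsilon = c(NA, NA, eps_used, eps_used, NA),
    correction = c("none", NA, correction, correction, NA),
    df1_corr = c(df_group, NA, eps_used * df_time, eps_used * df_int, NA),
    df2_corr = c(df_subj, NA, eps_used * df_err, eps_used * df_err, NA),
    p.value = c(p_between, NA, p_within(f_time, df_time),
                p_within(f_int, df_int), NA)
  )

  structure(list(table = table, epsilon_gg = eps$gg, epsilon_hf = eps$hf,
                 correction = correction, n_subjects = n, n_groups = g,
                 n_times = t_n, ss_total = ss_total),
            class = "cf_anova")
}

# Validate and normalize a long cohort table; returns subject/group/time as
# factors with `time` level order preserved from the data.
prepare_cohort <- function(data, outcome = NULL) {
  cf_assert(is.data.frame(data), "`data` must be a data frame.")
  if (!is.null(outcome)) {
    cf_assert("outcome" %in% names(data), "`data` has no `outcome` column.")
    data <- dplyr::filter(data, .data$outcome == !!outcome)
    cf_assert(nrow(data) > 0, sprintf("No rows for outcome `%s`.", outcome))
  }
  need <- c("subject", "group", "time", "value")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    cf_abort(sprintf("Missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  cf_assert(all(is.finite(data$value)), "`value` must be finite numeric.")
  time_levels <- if (is.factor(data$time)) levels(data$time) else
    unique(as.character(data$time))
  data <- dplyr::mutate(data,
                        subject = as.character(.data$subject),
                        group = factor(as.character(.data$group)),
                        time = factor(as.character(.data$time), levels = time_levels))
  counts <- dplyr::count(data, .data$subject, .data$time)
  per_subj <- tapply(counts$n, counts$subject, function(x) length(x) == length(time_levels) && all(x == 1))
  bad <- names(per_subj)[!per_subj]
  n_grp <- tapply(data$group, data$subject, function(x) length(unique(x)))
  bad <- union(bad, names(n_grp)[n_grp > 1])
  if (length(bad)) {
    cf_abort(sprintf(
      "Unbalanced design: subject(s) %s lack one row per time level within a single group.",
      paste(sort(bad), collapse = ", ")))
  }
  data
}

# Greenhouse-Geisser and Huynh-Feldt epsilons from the pooled within-group
# covariance of the t repeated measures. HF uses the Lecoutre-corrected
# multi-group form ((N-g+1)(t-1)eGG - 2) / ((t-1)(N - g - (t-1)eGG)).
sphericity_epsilons <- function(y, grp, n_j) {
  t_n <- ncol(y)
  n <- nrow(y)
  g <- nlevels(grp)
  centered <- y - rowsum(y, grp)[as.integer(grp), , drop = FALSE] / n_j[as.integer(grp)]
  s_pool <- crossprod(centered) / (n - g)
  m <- stats::contr.helmert(t_n)
  m <- sweep(m, 2, sqrt(colSums(m^2)), "/")  # orthonormal contrast columns
  a <- t(m) %*% s_pool %*% m
  gg <- sum(diag(a))^2 / ((t_n - 1) * sum(a^2))
  hf <- ((n - g + 1) * (t_n - 1) * gg - 2) /
    ((t_n - 1) * (n - g - (t_n - 1) * gg))
  list(gg = gg, hf = hf)
}

#' @export
print.cf_anova <- function(x, ...) {
  cat(sprintf(
    "<cf_anova> split-plot ANOVA: %d subjects, %d groups, %d time levels\n",
    x$n_subjects, x$n_groups, x$n_times))
  if (x$n_times > 2) {
    cat(sprintf("  sphericity: eps_GG = %.3f, eps_HF = %.3f -> %s correction\n",
                x$epsilon_gg, x$epsilon_hf, x$correction))
  }
  print(as.data.frame(x$table), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Tidy a mixed-ANOVA result
#' @param x A `cf_anova`.
#' @param ... Unused.
#' @return Tibble with one row per effect/stratum: `effect`, dfs, `sumsq`,
#'   `meansq`, `statistic`, `epsilon`, `correction`, corrected dfs,
#'   `p.value`.
#' @export
tidy.cf_anova <- function(x, ...) x$table

#' One-row summary of a mixed-ANOVA result
#' @param x A `cf_anova`.
#' @param ... Unused.
#' @return Tibble with design sizes, epsilons and the correction applied.
#' @export
glance.cf_anova <- function(x, ...) {
  tibble(n_subjects = x$n_subjects, n_groups = x$n_groups,
         n_times = x$n_times, epsilon_gg = x$epsilon_gg,
         epsilon_hf = x$epsilon_hf, correction = x$correction,
         ss_total = x$ss_total)
}

#' Tukey HSD post-hoc comparisons
#'
#' All pairwise group differences with studentized-range (Tukey-Kramer)
#' p-values. For `effect = "group"` the comparison is on subject means
#' across time levels, tested against the subjects-within-group stratum;
#' for `effect = "group_at_time"` it is on the raw values at one time level
#' (`at`), a plain one-way layout.
#'
#' @param data Tidy long cohort table (see [mixed_anova()]).
#' @param outcome Optional outcome filter.
#' @param effect `"group"` or `"group_at_time"`.
#' @param at Time level, required for `"group_at_time"`.
#' @param conf_level Confidence level for the Tukey intervals.
#' @return Tibble with one row per unordered pair: `group1`, `group2`,
#'   `estimate` (mean1 - mean2), `conf.low`, `conf.high`, `q`, `df`,
#'   `adj.p.value`.
#' @export
tukey_posthoc <- function(data, outcome = NULL,
                          effect = c("group", "group_at_time"), at = NULL,
                          conf_level = 0.95) {
  effect <- match.arg(effect)
  data <- prepare_cohort(data, outcome)
  if (effect == "group_at_time") {
    cf_assert(!is.null(at) && at %in% levels(data$time),
              "`at` must name a time level for effect = 'group_at_time'.")
    pts <- dplyr::filter(data, .data$time == !!at)
    vals <- pts$value
    grp <- droplevels(pts$group)
  } else {
    by_subj <- dplyr::summarise(dplyr::group_by(data, .data$subject, .data$group),
                                value = mean(.data$value), .groups = "drop")
    vals <- by_subj$value
    grp <- droplevels(by_subj$group)
  }
  g <- nlevels(grp)
  if (g < 2) cf_abort("Need at least 2 groups for post-hoc comparisons.")
  n_j <- as.vector(table(grp))
  means <- tapply(vals, grp, mean)
  df_err <- length(vals) - g
  cf_assert(df_err > 0, "Not enough subjects for a post-hoc error term.")
  mse <- sum((vals - means[as.integer(grp)])^2) / df_err
  pairs <- utils::combn(levels(grp), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    n1 <- n_j[levels(grp) == g1]; n2 <- n_j[levels(grp) == g2]
    est <- means[[g1]] - means[[g2]]
    se_q <- sqrt(mse / 2 * (1 / n1 + 1 / n2))
    q <- abs(est) / se_q
    crit <- qtukey(conf_level, g, df_err)
    tibble(group1 = g1, group2 = g2, estimate = est,
           conf.low = est - crit * se_q, conf.high = est + crit * se_q,
           q = q, df = df_err,
           adj.p.value = ptukey(q, g, df_err, lower.tail = FALSE))
  })
}

#' Pearson product-moment correlation
#'
#' Standard Pearson correlation with its t-test, validated for the small-n
#' settings used here (n >= 3, non-degenerate variance).
#'
#' @param x,y Equal-length numeric vectors.
#' @return One-row tibble: `estimate` (r), `n`, `statistic` (t), `df`,
#'   `p.value`.
#' @examples
#' pearson_r(1:10, (1:10) * -2)
#' @export
pearson_r <- function(x, y) {
  cf_assert(is.numeric(x) && is.numeric(y), "`x` and `y` must be numeric.")
  cf_assert(length(x) == length(y), "`x` and `y` must have equal length.")
  cf_assert(length(x) >= 3, "Need at least 3 observations.")
  cf_assert(all(is.finite(x)) && all(is.finite(y)), "Inputs must be finite.")
  if (sd(x) == 0 || sd(y) == 0) {
    cf_abort("Correlation undefined: an input has zero variance.")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble(estimate = unname(ct$estimate), n = length(x),
         statistic = unname(ct$statistic), df = unname(ct$parameter),
         p.value = ct$p.value)
}

#' Plot a pre/post cohort outcome
#'
#' Subject trajectories over time, faceted by group, with group means
#' overlaid — the usual first look before the mixed ANOVA.
#'
#' @param data Tidy long cohort table.
#' @param outcome Optional outcome filter.
#' @return A ggplot object.
#' @export
plot_cohort <- function(data, outcome = NULL) {
  data <- prepare_cohort(data, outcome)
  means <- dplyr::summarise(dplyr::group_by(data, .data$group, .data$time),
                            value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(data, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject), alpha = 0.3) +
    ggplot2::geom_line(data = means, ggplot2::aes(group = .data$group),
                       colour = "firebrick", linewidth = 1.2) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = NULL, y = "Value") +
    ggplot2::theme_minimal()
}
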