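make_trend_log <- function(walk_min_by_week = list(10, 12, 15),
                           meal_kcal_by_week = list(600, 550, 480)) {
  rows <- list()
  for (w in 1:3) {
    for (d in 1:7) {
      day0 <- ts0() + ((w - 1) * 7 + d - 1) * 86400
      for (v in walk_min_by_week[[w]]) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          start = day0 + 8 * 3600, end = day0 + 8 * 3600 + v * 60,
          kind = "activity", label = "walking", duration_min = v,
          kcal = 3.5 * 70 * v / 60
        )
      }
      for (v in meal_kcal_by_week[[w]]) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          start = day0 + 12.5 * 3600, end = day0 + 12.5 * 3600 + 60,
          kind = "food", label = "F101", duration_min = 1, kcal = v
        )
      }
    }
  }
  ll <- dplyr::bind_rows(rows)
  class(ll) <- c("lifelog", class(ll))
  ll
}

test_that("weekly trends classify healthy directions per metric", {
  ll <- make_trend_log()
  tw <- weekly_trend(ll, "walk_length_minutes")
  expect_equal(c(tw$week1_median, tw$week2_median, tw$week3_median),
               c(10, 12, 15))
  expect_equal(tw$direction, "positive") # longer walks
  tm <- weekly_trend(ll, "meal_kcal")
  expect_equal(tm$direction, "positive") # fewer calories
  # reversed meals: negative
  ll2 <- make_trend_log(meal_kcal_by_week = list(480, 550, 600))
  expect_equal(weekly_trend(ll2, "meal_kcal")$direction, "negative")
  # short log errors
  short <- ll[ll$start < ts0() + 10 * 86400, ]
  expect_error(weekly_trend(short, "meal_kcal"), "3 weeks")
})

test_that("a week without events flags insufficient data", {
  ll <- make_trend_log()
  gap <- ll[!(ll$kind == "food" &
                ll$start >= ts0() + 7 * 86400 &
                ll$start < ts0() + 14 * 86400), ]
  tm <- weekly_trend(gap, "meal_kcal")
  expect_true(tm$insufficient_data)
  expect_true(is.na(tm$direction))
  # the walk metric is untouched
  expect_false(weekly_trend(gap, "walk_length_minutes")$insufficient_data)
})

test_that("fisher enumeration matches closed cases and the stats oracle", {
  # both extreme tables of a 1/1 margin have probability 1/2
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2))$p_value, 1)
  # the trial's diet table
  expect_equal(fisher_exact_2x2(matrix(c(7, 3, 2, 5), 2))$p_value,
               0.1534, tolerance = 1e-3)
  # independent oracle across random tables
  set.seed(10)
  for (i in 1:25) {
    m <- matrix(rpois(4, 4) + 1, 2)
    expect_equal(
      fisher_exact_2x2(m)$p_value,
      stats::fisher.test(m)$p.value,
      tolerance = 1e-8
    )
  }
})

test_that("fisher p is invariant under transposition and row/column
           swaps, and probabilities sum to one", {
  m <- matrix(c(7, 2, 2, 6), 2)
  p <- fisher_exact_2x2(m)$p_value
  expect_equal(fisher_exact_2x2(t(m))$p_value, p)
  expect_equal(fisher_exact_2x2(m[2:1, ])$p_value, p)
  expect_equal(fisher_exact_2x2(m[, 2:1])$p_value, p)
  expect_true(p > 0 && p <= 1)
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), "margins")
})

test_that("mann-whitney exact enumeration matches hand counts and
           wilcox.test", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$u, 0)
  expect_equal(r$p_value, 2 / 6) # all C(4,2) splits enumerated
  expect_equal(r$method, "exact")
  # identity U_a + U_b = n_a * n_b and zero effect for identical samples
  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(4); b <- rnorm(5)
    ua <- mann_whitney_u(a, b)$u
    ub <- mann_whitney_u(b, a)$u
    expect_equal(ua + ub, 20)
  }
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$effect_size, 0)
  # oracle agreement (no ties -> wilcox exact)
  set.seed(6)
  a <- rnorm(5); b <- rnorm(6)
  expect_equal(
    mann_whitney_u(a, b)$p_value,
    stats::wilcox.test(a, b, exact = TRUE)$p.value,
    tolerance = 1e-8
  )
  # large-sample normal path tracks wilcox.test without continuity corr.
  set.seed(7)
  a <- rnorm(20); b <- rnorm(25, 0.5)
  expect_equal(
    mann_whitney_u(a, b)$p_value,
    stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value,
    tolerance = 1e-6
  )
})

test_that("pooled t and Cohen's d match hand computation and t.test", {
  r <- two_sample_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(abs(r$cohens_d), 1) # mean diff 1, pooled SD 1
  expect_equal(abs(r$t), sqrt(3 * 3 / 6), tolerance = 1e-10)
  expect_equal(r$df, 4)
  oracle <- stats::t.test(c(1, 2, 3), c(2, 3, 4), var.equal = TRUE)
  expect_equal(r$t, unname(oracle$statistic))
  expect_equal(r$p_value, oracle$p.value)
  # degenerate cases
  same <- two_sample_t(c(2, 2), c(2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$cohens_d, 0)
  expect_error(two_sample_t(c(0, 0), c(1, 1)), "Zero pooled variance")
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
})

test_that("analyze_trial assembles tables with insufficient-data users
           as non-positive and runs both tests", {
  tr <- simulate_trial(
    4, 3, scenario_config(days = 21, seed = 31, intervention_effect = 0.3)
  )
  rep <- analyze_trial(tr)
  expect_s3_class(rep, "trial_report")
  for (m in c("walk_length_minutes", "meal_kcal")) {
    tab <- rep$tables[[m]]
    expect_equal(sum(tab), 7)
    expect_equal(unname(rowSums(tab)), c(4, 3))
  }
  expect_true(all(rep$tests$fisher_p > 0 & rep$tests$fisher_p <= 1))
  expect_equal(nrow(tidy(rep)), 14) # 7 users x 2 metrics
  g <- glance(rep)
  expect_equal(g$n_users, 7)
  # ratings comparison plugs into the exact Mann-Whitney
  rep2 <- analyze_trial(tr, ratings = list(
    experimental = c(4, 5, 3, 4), control = c(2, 1, 3)
  ))
  expect_false(is.null(rep2$ratings_test))
  expect_equal(rep2$ratings_test$method, "exact")
  # single-arm designs are rejected
  bad <- tr
  bad$design$arm <- "experimental"
  expect_error(analyze_trial(bad), "Both arms")
})

test_that("the trial autoplot renders weekly medians by arm", {
  tr <- simulate_trial(2, 2, scenario_config(days = 21, seed = 13))
  rep <- analyze_trial(tr)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gt(length(built$data), 0)
})
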