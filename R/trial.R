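#' Weekly-median trend for one user
#'
#' Computes per-week medians (weeks 1-3 from the first day in the log) of
#' either walking event lengths in minutes (`walk_length_minutes`) or
#' per-meal calories (`meal_kcal`, meals only — snacks excluded), and
#' classifies the week-1 to week-3 change in the metric's healthy
#' direction: longer walks are positive, lower meal calories are
#' positive. A week without events flags `insufficient_data` and leaves
#' the direction undefined.
#'
#' @param lifelog A `lifelog` tibble spanning at least 3 weeks.
#' @param metric `"walk_length_minutes"` or `"meal_kcal"`.
#' @return One-row tibble: `metric`, `week1_median`, `week2_median`,
#'   `week3_median`, `direction` (`"positive"`/`"negative"`/`NA`),
#'   `insufficient_data`.
#' @export
weekly_trend <- function(lifelog,
                         metric = c("walk_length_minutes", "meal_kcal")) {
  metric <- match.arg(metric)
  ll <- as_tibble(lifelog)
  if (nrow(ll) == 0) abort("Empty life log.")
  t0 <- as.POSIXct(
    format(min(ll$start), "%Y-%m-%d 00:00:00"), tz = "UTC"
  )
  span_days <- as.numeric(max(ll$end) - t0, units = "days")
  if (span_days < 15) {
    abort("Life log must span at least 3 weeks for a trend.")
  }
  if (metric == "walk_length_minutes") {
    ev <- ll[ll$kind %in% c("activity", "manual_exercise") &
               ll$label == "walking", ]
    val <- ev$duration_min
  } else {
    ev <- ll[ll$kind == "food", ]
    ev <- ev[is_meal(ev$start, ev$kcal), ]
    val <- ev$kcal
  }
  week <- floor(as.numeric(ev$start - t0, units = "days") / 7) + 1
  med <- vapply(1:3, function(w) {
    x <- val[week == w]
    if (length(x) == 0) NA_real_ else median(x)
  }, numeric(1))
  insufficient <- anyNA(med)
  direction <- NA_character_
  if (!insufficient) {
    delta <- med[3] - med[1]
    up_good <- metric == "walk_length_minutes"
    direction <- if ((up_good && delta > 0) || (!up_good && delta < 0)) {
      "positive"
    } else {
      "negative"
    }
  }
  tibble(
    metric = metric,
    week1_median = med[1], week2_median = med[2], week3_median = med[3],
    direction = direction,
    insufficient_data = insufficient
  )
}

#' Exact Fisher test for a 2x2 table
#'
#' Two-sided p-value by full hypergeometric enumeration with fixed
#' margins: the sum of probabilities of all tables whose point
#' probability does not exceed the observed table's (with a small
#' relative tolerance for floating-point ties). Invariant under
#' transposition and row/column swaps.
#'
#' @param table A 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return One-row tibble: `p_value`, `n` (table total).
#' @examples
#' fisher_exact_2x2(matrix(c(7, 3, 2, 5), 2)) # p ~= 0.153
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2)) || any(m < 0) || any(m != round(m))) {
    abort("`table` must be a 2x2 matrix of non-negative integers.")
  }
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ])
  c1 <- sum(m[, 1]); c2 <- sum(m[, 2])
  if (min(r1, r2, c1, c2) == 0) {
    abort("All margins of the 2x2 table must be positive.")
  }
  n <- sum(m)
  a_range <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, a_range) + lchoose(r2, c1 - a_range) - lchoose(n, c1)
  p_obs <- logp[a_range == m[1, 1]]
  p <- sum(exp(logp)[logp <= p_obs + 1e-7])
  tibble(p_value = min(p, 1), n = n)
}

#' Mann-Whitney U test
#'
#' Rank-sum test with the U statistic for the first sample. For combined
#' sizes of 12 or fewer the two-sided p-value is exact, enumerated over
#' all assignments of the pooled values to the two groups (which handles
#' ties as a permutation test); larger samples use the normal
#' approximation with the tie-corrected variance. The effect size is the
#' rank-biserial correlation `2U/(n1 n2) - 1`.
#'
#' @param a,b Numeric samples (non-empty).
#' @param exact_max Combined-size threshold for exact enumeration.
#' @return One-row tibble: `u`, `p_value`, `effect_size`, `method`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4)) # U = 0, exact p = 1/3
#' @export
mann_whitney_u <- function(a, b, exact_max = 12) {
  if (length(a) == 0 || length(b) == 0) {
    abort("Both samples must be non-empty.")
  }
  n1 <- length(a); n2 <- length(b)
  u_of <- function(x, pooled_ranks, idx) {
    sum(pooled_ranks[idx]) - length(idx) * (length(idx) + 1) / 2
  }
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= exact_max) {
    splits <- utils::combn(n1 + n2, n1)
    us <- apply(splits, 2, function(idx) u_of(pooled, r, idx))
    p <- 2 * min(mean(us <= u), mean(us >= u))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    nt <- n1 + n2
    sigma2 <- n1 * n2 / 12 *
      (nt + 1 - sum(ties^3 - ties) / (nt * (nt - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      p <- 2 * pnorm(-abs((u - mu) / sqrt(sigma2)))
    }
    method <- "normal"
  }
  tibble(
    u = u,
    p_value = min(p, 1),
    effect_size = 2 * u / (n1 * n2) - 1,
    method = method
  )
}

#' Pooled two-sample t test with Cohen's d
#'
#' Student's t with pooled variance and `n1 + n2 - 2` degrees of freedom;
#' Cohen's d is the mean difference over the pooled standard deviation.
#' Degenerate inputs with zero pooled variance return `t = 0, d = 0` when
#' the means agree and are an error otherwise.
#'
#' @param a,b Numeric samples with at least 2 values each.
#' @return One-row tibble: `t`, `df`, `p_value`, `cohens_d`,
#'   `mean_diff` (`mean(a) - mean(b)`).
#' @export
two_sample_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) abort("Both samples need at least 2 values.")
  df <- n1 + n2 - 2
  diff <- mean(a) - mean(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / df
  if (sp2 == 0) {
    if (diff != 0) {
      abort("Zero pooled variance with unequal means.")
    }
    return(tibble(t = 0, df = df, p_value = 1, cohens_d = 0,
                  mean_diff = 0))
  }
  t_stat <- diff / sqrt(sp2 * (1 / n1 + 1 / n2))
  tibble(
    t = t_stat,
    df = df,
    p_value = 2 * stats::pt(-abs(t_stat), df),
    cohens_d = diff / sqrt(sp2),
    mean_diff = diff
  )
}

#' Analyze a two-arm trial
#'
#' Runs the full analysis plan over a simulated (or assembled) trial:
#' per-user weekly-median trends for walking length and meal calories,
#' 2x2 trend tables by arm (users with insufficient data count as
#' non-positive), an exact Fisher test per metric, and a pooled t test
#' with Cohen's d on each user's week-3 minus week-1 median change.
#' Optional suggestion-rating vectors are compared with the exact
#' Mann-Whitney U test.
#'
#' @param trial A `trial` from [simulate_trial()], or a list with
#'   `design` (tibble `user_id`, `arm`) and `users` (named list of
#'   `simulated_user` or `lifelog` objects).
#' @param ratings Optional list with numeric `experimental` and `control`
#'   rating vectors.
#' @param food_table,mets Lookup tables for life-log conversion.
#' @return A `trial_report`: list with `trends` (per user x metric),
#'   `tables` (2x2 matrices per metric), `tests` (Fisher p per metric),
#'   `changes` (t test per metric), and `ratings_test` (or `NULL`).
#' @export
analyze_trial <- function(trial, ratings = NULL,
                          food_table = read_food_table(),
                          mets = met_table()) {
  design <- trial$design
  if (length(unique(design$arm)) < 2 ||
        any(table(design$arm) == 0)) {
    abort("Both arms must contain at least one user.")
  }
  logs <- lapply(trial$users, function(u) {
    if (is_lifelog(u)) u else as_lifelog(u, food_table, mets)
  })
  metrics <- c("walk_length_minutes", "meal_kcal")
  trends <- map(design$user_id, function(uid) {
    arm <- design$arm[design$user_id == uid]
    map(metrics, function(m) {
      weekly_trend(logs[[uid]], m) %>%
        mutate(user_id = uid, arm = arm)
    }) %>% list_rbind()
  }) %>% list_rbind()

  tables <- lapply(metrics, function(m) {
    tr <- trends[trends$metric == m, ]
    # insufficient-data users count as non-positive
    pos <- !is.na(tr$direction) & tr$direction == "positive"
    tab <- rbind(
      experimental = c(
        positive = sum(pos & tr$arm == "experimental"),
        non_positive = sum(!pos & tr$arm == "experimental")
      ),
      control = c(
        positive = sum(pos & tr$arm == "control"),
        non_positive = sum(!pos & tr$arm == "control")
      )
    )
    tab
  })
  names(tables) <- metrics

  tests <- map(metrics, function(m) {
    p <- tryCatch(fisher_exact_2x2(tables[[m]])$p_value,
                  error = function(e) NA_real_)
    tibble(metric = m, fisher_p = p)
  }) %>% list_rbind()

  changes <- map(metrics, function(m) {
    tr <- trends[trends$metric == m & !trends$insufficient_data, ]
    delta <- tr$week3_median - tr$week1_median
    if (m == "meal_kcal") delta <- -delta # healthy direction positive
    a <- delta[tr$arm == "experimental"]
    b <- delta[tr$arm == "control"]
    if (length(a) >= 2 && length(b) >= 2) {
      two_sample_t(a, b) %>% mutate(metric = m, .before = 1)
    } else {
      tibble(metric = m, t = NA_real_, df = NA_real_, p_value = NA_real_,
             cohens_d = NA_real_, mean_diff = NA_real_)
    }
  }) %>% list_rbind()

  ratings_test <- NULL
  if (!is.null(ratings)) {
    ratings_test <- mann_whitney_u(ratings$experimental, ratings$control)
  }

  structure(
    list(
      trends = trends, tables = tables, tests = tests,
      changes = changes, ratings_test = ratings_test
    ),
    class = "trial_report"
  )
}

#' @export
#' @method tidy trial_report
tidy.trial_report <- function(x, ...) {
  x$trends %>%
    select(
      "user_id", "arm", "metric", "week1_median", "week2_median",
      "week3_median", "direction", "insufficient_data"
    )
}

#' @export
#' @method glance trial_report
glance.trial_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    x$tests,
    names_from = "metric", values_from = "fisher_p",
    names_prefix = "fisher_p_"
  )
  wide$n_users <- dplyr::n_distinct(x$trends$user_id)
  wide
}

#' @export
print.trial_report <- function(x, ...) {
  cat("<trial_report>\n")
  for (m in names(x$tables)) {
    cat(sprintf(
      "  %s: Fisher p = %.4f\n", m,
      x$tests$fisher_p[x$tests$metric == m]
    ))
    print(x$tables[[m]])
  }
  invisible(x)
}
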