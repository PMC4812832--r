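#' Projected weekly calorie impact of activity clusters
#'
#' The exploit score of a repeated activity: occurrences per week
#' (frequency over the trailing window, rescaled to 7 days) times the
#' mean calories burned per instance. A 30-minute walk done 5 times a
#' week (about 122.5 kcal each at 3.5 MET and 70 kg) therefore outranks a
#' weekly 420-kcal gym session.
#'
#' @param clusters `behavior_clusters` rows of type `trajectory` or
#'   `manual_exercise_type`; stationary clusters are rejected (use
#'   [small_change_for_stationary()]).
#' @return Numeric vector of projected weekly kcal, one per row.
#' @export
score_activity_cluster <- function(clusters) {
  cl <- as_tibble(clusters)
  if (any(cl$cluster_type == "stationary_place")) {
    abort(paste(
      "Stationary clusters are not scored directly;",
      "use small_change_for_stationary()."
    ))
  }
  freq_wk <- cl$frequency / (cl$window_days %||% 14) * 7
  freq_wk * cl$per_instance_kcal
}

#' Small-change suggestions for stationary clusters
#'
#' For each stationary place, prescribes a short walk
#' (`config$small_change_walk_minutes`, default 3) for every hour spent
#' stationary there. The projected impact is the weekly stationary hours
#' at the place times the calories of one prescribed walk
#' (`MET_walking x weight x minutes/60`), and competes in the same
#' ranking as other activity suggestions: 25 one-hour office episodes a
#' week at 70 kg project 25 x 12.25 = 306.25 kcal, beating a
#' once-a-week 245-kcal gym visit.
#'
#' @param clusters `behavior_clusters` rows of type `stationary_place`.
#' @param weight_kg Body weight.
#' @param mets MET table.
#' @param config [engine_config()].
#' @return Tibble with one suggestion row per cluster:
#'   `target_cluster_id`, `walk_minutes`, `kcal_per_instance`,
#'   `projected_weekly_kcal`, `frequency`, `text`.
#' @export
small_change_for_stationary <- function(clusters, weight_kg,
                                        mets = met_table(),
                                        config = engine_config()) {
  cl <- as_tibble(clusters)
  if (nrow(cl) && any(cl$cluster_type != "stationary_place")) {
    abort("All clusters must be of type 'stationary_place'.")
  }
  wm <- config$small_change_walk_minutes
  kcal_per_walk <- activity_kcal("walking", wm, weight_kg, mets)
  freq_wk <- cl$frequency / (cl$window_days %||% 14) * 7
  weekly_hours <- freq_wk * cl$per_instance_duration / 60
  tibble(
    target_cluster_id = cl$cluster_id,
    walk_minutes = wm,
    kcal_per_instance = kcal_per_walk,
    projected_weekly_kcal = weekly_hours * kcal_per_walk,
    frequency = cl$frequency,
    text = sprintf(
      "Add a %d-minute walk for every hour you spend stationary near (%.4f, %.4f).",
      as.integer(wm), cl$rep_lat, cl$rep_lon
    )
  )
}

#' Split scored clusters into exploit and explore pools
#'
#' Frequent clusters (at least `config$frequent_min_count` occurrences in
#' the trailing window) feed exploit and small-change suggestions;
#' clusters seen at least once but below the threshold are explore
#' candidates. Behaviors never observed are never suggested — having done
#' something before, even rarely, is taken as evidence the user has the
#' skills for it.
#'
#' @param clusters A `behavior_clusters` tibble.
#' @param config [engine_config()].
#' @return A list with tibbles `frequent` and `infrequent`.
#' @export
partition_exploit_explore <- function(clusters, config = engine_config()) {
  cl <- as_tibble(clusters)
  list(
    frequent = filter(cl, .data$frequency >= config$frequent_min_count),
    infrequent = filter(
      cl,
      .data$frequency >= 1, .data$frequency < config$frequent_min_count
    )
  )
}

#' Generate a daily batch of ranked suggestions
#'
#' Emits the day's suggestions for one category under the fixed
#' exploit/explore split: with `n = 10` and `exploit_fraction = 0.9`,
#' exactly 9 exploit slots and 1 explore slot. Activity exploit slots are
#' the top frequent clusters by projected weekly calorie burn, with
#' small-change walk suggestions for stationary places competing in the
#' same ranking; the explore slot is a uniform draw from infrequent
#' clusters whose per-instance burn is above the candidate median. Food
#' exploit slots are frequent low-calorie meal/snack clusters in
#' ascending per-instance kcal (frequent clusters above the user's
#' goal-dependent calorie cutoff are framed as "avoid" suggestions by
#' [food_avoid_suggestions()] and do not occupy these slots); the explore
#' slot draws from infrequent below-median clusters. An empty explore
#' pool backfills from exploit; fewer than `n` candidates emit as many
#' as exist.
#'
#' @param clusters A `behavior_clusters` tibble for one user.
#' @param category `"activity"` or `"food"`.
#' @param profile [user_profile()] (weight for METS, goal for the avoid
#'   cutoff).
#' @param config [engine_config()].
#' @param date Batch date (`Date` or string); combined with
#'   `config$rng_seed` to seed the explore draw deterministically.
#' @param mets MET table.
#' @return A `suggestion_batch` tibble: `date`, `category`, `rank`,
#'   `arm` (`exploit`/`explore`/`small_change`), `target_cluster_id`,
#'   `projected_weekly_kcal`, `per_instance_kcal`, `frequency`, `text`.
#' @export
generate_daily_batch <- function(clusters, category = c("activity", "food"),
                                 profile, config = engine_config(),
                                 date = Sys.Date(), mets = met_table()) {
  category <- match.arg(category)
  cl <- as_tibble(clusters)
  cl$.created <- seq_len(nrow(cl)) # earlier-created cluster wins ties
  if (category == "activity") {
    cand <- activity_candidates(cl, profile, config, mets)
  } else {
    cand <- food_candidates(cl, profile, config)
  }
  n <- if (category == "activity") config$n_activity else config$n_food
  n_exploit <- floor(n * config$exploit_fraction)
  freq <- cand[cand$frequency >= config$frequent_min_count, ]
  infreq <- cand[cand$frequency >= 1 &
                   cand$frequency < config$frequent_min_count, ]
  # exploit ranking
  ord <- if (category == "activity") {
    order(-freq$score, freq$.created)
  } else {
    order(freq$per_instance_kcal, freq$.created)
  }
  exploit <- head(freq[ord, ], n_exploit)
  # explore pool: calorie-direction filter against the candidate median
  med <- median(cand$per_instance_kcal)
  pool <- if (category == "activity") {
    infreq[infreq$per_instance_kcal > med, ]
  } else {
    infreq[infreq$per_instance_kcal < med, ]
  }
  n_explore <- n - nrow(exploit)
  explore <- pool[0, ]
  if (nrow(pool) > 0 && n_explore > 0) {
    draw_seed <- derive_seed(config$rng_seed,
                             paste(category, format(date)))
    take <- with_seed(draw_seed, {
      sample(nrow(pool), min(n_explore, 1L))
    })
    explore <- pool[take, ]
    explore$arm <- "explore"
    n_explore <- n_explore - nrow(explore)
  }
  if (n_explore > 0) { # backfill from remaining exploit candidates
    extra <- freq[ord, ][-seq_len(nrow(exploit)), ]
    extra <- head(extra, n_explore)
    exploit <- bind_rows(exploit, extra)
  }
  out <- bind_rows(exploit, explore)
  if (nrow(out) == 0) {
    message(sprintf("No %s suggestion candidates available.", category))
  } else if (nrow(out) < n) {
    message(sprintf(
      "Only %d of %d %s suggestions available.", nrow(out), n, category
    ))
  }
  out %>%
    mutate(
      date = as.Date(date),
      category = category,
      rank = row_number(),
      suggestion_id = sprintf("%s_%s_%02d", format(as.Date(date)),
                              category, row_number())
    ) %>%
    select(
      "suggestion_id", "date", "category", "rank", "arm",
      "target_cluster_id", "projected_weekly_kcal", "per_instance_kcal",
      "frequency", "text"
    )
}

activity_candidates <- function(cl, profile, config, mets) {
  parts <- list()
  act <- cl %>%
    filter(.data$cluster_type %in% c("trajectory", "manual_exercise_type"))
  if (nrow(act)) {
    act$score <- score_activity_cluster(act)
    parts$act <- act %>%
      mutate(
        arm = "exploit",
        target_cluster_id = .data$cluster_id,
        projected_weekly_kcal = .data$score,
        text = activity_text(act)
      ) %>%
      select(
        "target_cluster_id", "arm", "score", "projected_weekly_kcal",
        "per_instance_kcal", "frequency", "text", ".created"
      )
  }
  stat <- cl %>%
    filter(.data$cluster_type == "stationary_place",
           .data$cluster_id != "unlocated")
  if (nrow(stat)) {
    sc <- small_change_for_stationary(stat, profile$weight_kg, mets,
                                      config)
    parts$stat <- sc %>%
      mutate(
        arm = "small_change",
        score = .data$projected_weekly_kcal,
        per_instance_kcal = .data$kcal_per_instance,
        .created = stat$.created
      ) %>%
      select(
        "target_cluster_id", "arm", "score", "projected_weekly_kcal",
        "per_instance_kcal", "frequency", "text", ".created"
      )
  }
  out <- list_rbind(parts)
  if (is.null(out) || nrow(out) == 0) {
    tibble(
      target_cluster_id = character(), arm = character(),
      score = numeric(), projected_weekly_kcal = numeric(),
      per_instance_kcal = numeric(), frequency = integer(),
      text = character(), .created = integer()
    )
  } else {
    out
  }
}

activity_text <- function(act) {
  ifelse(
    act$cluster_type == "manual_exercise_type",
    sprintf(
      "Keep up your %s sessions (~%.0f min, ~%.0f kcal each).",
      sub("^manual:", "", act$label), act$per_instance_duration,
      act$per_instance_kcal
    ),
    sprintf(
      "Keep doing your usual %.0f-minute %s near (%.4f, %.4f) (~%.0f kcal each time).",
      act$per_instance_duration, act$label, act$rep_lat, act$rep_lon,
      act$per_instance_kcal
    )
  )
}

food_candidates <- function(cl, profile, config) {
  food <- cl %>% filter(.data$cluster_type %in% c("meal", "snack"))
  if (nrow(food) == 0) {
    return(tibble(
      target_cluster_id = character(), arm = character(),
      score = numeric(), projected_weekly_kcal = numeric(),
      per_instance_kcal = numeric(), frequency = integer(),
      text = character(), .created = integer()
    ))
  }
  cutoff <- config$avoid_kcal_cutoff[[profile$goal]]
  freq_wk <- food$frequency / (food$window_days %||% 14) * 7
  food %>%
    mutate(
      arm = "exploit",
      target_cluster_id = .data$cluster_id,
      score = -.data$per_instance_kcal,
      projected_weekly_kcal = freq_wk * .data$per_instance_kcal,
      text = sprintf(
        "Continue choosing %s (~%.0f kcal per serving).",
        .data$rep_name, .data$per_instance_kcal
      )
    ) %>%
    # frequent high-calorie clusters are "avoid" material, not exploit
    filter(!(.data$frequency >= config$frequent_min_count &
               .data$per_instance_kcal > cutoff)) %>%
    select(
      "target_cluster_id", "arm", "score", "projected_weekly_kcal",
      "per_instance_kcal", "frequency", "text", ".created"
    )
}

#' Avoid/reduce framing for frequent high-calorie meal clusters
#'
#' Frequent meal or snack clusters whose per-instance calories exceed the
#' user's goal-dependent cutoff are rendered as "avoid or reduce"
#' suggestions. They are reported alongside the daily batch but never
#' occupy its ranked exploit slots.
#'
#' @param clusters A `behavior_clusters` tibble.
#' @param profile [user_profile()].
#' @param config [engine_config()].
#' @return Tibble of avoid suggestions (possibly empty).
#' @export
food_avoid_suggestions <- function(clusters, profile,
                                   config = engine_config()) {
  cl <- as_tibble(clusters) %>%
    filter(.data$cluster_type %in% c("meal", "snack"))
  cutoff <- config$avoid_kcal_cutoff[[profile$goal]]
  cl %>%
    filter(.data$frequency >= config$frequent_min_count,
           .data$per_instance_kcal > cutoff) %>%
    mutate(
      arm = "avoid",
      target_cluster_id = .data$cluster_id,
      text = sprintf(
        "Consider cutting back on %s (~%.0f kcal per serving, %d times in %d days).",
        .data$rep_name, .data$per_instance_kcal, .data$frequency,
        as.integer(.data$window_days %||% 14)
      )
    ) %>%
    select(
      "target_cluster_id", "arm", "per_instance_kcal", "frequency", "text"
    )
}

#' Draw generic control-arm suggestions
#'
#' Uniform sample without replacement from a pool of prescriptive
#' healthy-living suggestions (the control condition of a trial).
#'
#' @param pool Tibble with at least a `text` column (see
#'   [generic_suggestion_pool()]).
#' @param n Number of suggestions (capped at the pool size).
#' @param seed Integer seed.
#' @return Tibble of sampled rows with a `rank` column.
#' @export
draw_generic_suggestions <- function(pool, n, seed = 1) {
  if (nrow(pool) == 0) abort("`pool` must be non-empty.")
  k <- min(n, nrow(pool))
  take <- with_seed(seed, sample(nrow(pool), k))
  pool[take, ] %>% mutate(rank = row_number())
}
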