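#' Create a user profile
#'
#' A profile holds the anthropometrics and anchor locations the simulator,
#' energy model and suggestion engine need: body weight drives the METS
#' calorie formula (kcal = MET x kg x hours), and the home/office anchors
#' define where routine stationary episodes and commute walks happen.
#'
#' @param user_id Character scalar identifying the user.
#' @param weight_kg Body weight in kilograms (> 0).
#' @param height_cm Height in centimeters (> 0).
#' @param goal One of `"lose"`, `"maintain"`, `"gain"`; steers which frequent
#'   meal clusters are framed as "avoid" food suggestions.
#' @param home,office Named numeric vectors `c(lat = , lon = )` in WGS84
#'   decimal degrees. Generated profiles keep them at least 500 m apart.
#' @return A list of class `user_profile`.
#' @examples
#' user_profile("u1", weight_kg = 70)
#' @export
user_profile <- function(user_id,
                         weight_kg = 70,
                         height_cm = 170,
                         goal = c("maintain", "lose", "gain"),
                         home = c(lat = 42.4440, lon = -76.5019),
                         office = c(lat = 42.4534, lon = -76.4735)) {
  goal <- match.arg(goal)
  if (!is.character(user_id) || length(user_id) != 1L || !nzchar(user_id)) {
    abort("`user_id` must be a non-empty string.")
  }
  stopifnot_scalar_number(weight_kg, "weight_kg", min = 0, strict = TRUE)
  stopifnot_scalar_number(height_cm, "height_cm", min = 0, strict = TRUE)
  for (p in list(home = home, office = office)) {
    if (!all(c("lat", "lon") %in% names(p))) {
      abort("`home` and `office` must be named c(lat=, lon=) vectors.")
    }
  }
  if (abs(home[["lat"]]) > 90 || abs(office[["lat"]]) > 90) {
    abort("Latitudes must lie in [-90, 90].")
  }
  structure(
    list(
      user_id = user_id, weight_kg = weight_kg, height_cm = height_cm,
      goal = goal,
      home = home[c("lat", "lon")], office = office[c("lat", "lon")]
    ),
    class = "user_profile"
  )
}

#' Configure a simulation scenario
#'
#' Defines the behavioral regime of a synthetic user: how often they walk
#' their commute, how often they exercise, what their meals and snacks look
#' like, how noisy the GPS is, and an optional intervention effect applied
#' from week 2 onward (walk durations scaled by `1 + intervention_effect`,
#' meal calories by `1 - intervention_effect`).
#'
#' @param days Number of simulated days (>= 1); trials use 21 (three weeks).
#' @param seed Integer root seed; per-user streams are derived from
#'   `(seed, user_id)` so adding users never perturbs existing ones.
#' @param routine_walks_per_week Expected number of walked morning commutes
#'   per week (each day walks with probability `rate / 7`).
#' @param gym_visits_per_week Expected number of running-loop workouts per
#'   week.
#' @param meal_kcal_mean,meal_kcal_sd Lognormal meal-calorie target (kcal).
#' @param snack_kcal_mean,snack_kcal_sd Lognormal snack-calorie target.
#' @param snacks_per_day Poisson rate of between-meal snacks.
#' @param gps_noise_sd Isotropic GPS noise, meters, added in the local
#'   tangent plane.
#' @param intervention_effect Signed fraction in (-1, 1); 0 means no
#'   behavior change between weeks.
#' @return A list of class `scenario_config`.
#' @examples
#' scenario_config(days = 21, seed = 1, intervention_effect = 0.3)
#' @export
scenario_config <- function(days = 21,
                            seed = 1,
                            routine_walks_per_week = 5,
                            gym_visits_per_week = 1,
                            meal_kcal_mean = 600,
                            meal_kcal_sd = 150,
                            snack_kcal_mean = 180,
                            snack_kcal_sd = 60,
                            snacks_per_day = 1,
                            gps_noise_sd = 10,
                            intervention_effect = 0) {
  if (!is.numeric(days) || length(days) != 1L || is.na(days) || days < 1) {
    abort("`days` must be a positive integer (>= 1).")
  }
  days <- as.integer(days)
  stopifnot_scalar_number(seed, "seed")
  for (nm in c(
    "routine_walks_per_week", "gym_visits_per_week",
    "meal_kcal_mean", "meal_kcal_sd", "snack_kcal_mean",
    "snack_kcal_sd", "snacks_per_day", "gps_noise_sd"
  )) {
    stopifnot_scalar_number(get(nm), nm, min = 0)
  }
  stopifnot_scalar_number(intervention_effect, "intervention_effect")
  if (abs(intervention_effect) >= 1) {
    abort("`intervention_effect` must lie strictly between -1 and 1.")
  }
  structure(
    list(
      days = days, seed = as.integer(seed) %% 2147483647L,
      routine_walks_per_week = routine_walks_per_week,
      gym_visits_per_week = gym_visits_per_week,
      meal_kcal_mean = meal_kcal_mean, meal_kcal_sd = meal_kcal_sd,
      snack_kcal_mean = snack_kcal_mean, snack_kcal_sd = snack_kcal_sd,
      snacks_per_day = snacks_per_day,
      gps_noise_sd = gps_noise_sd,
      intervention_effect = intervention_effect
    ),
    class = "scenario_config"
  )
}

#' Configure the suggestion engine
#'
#' @param n_activity,n_food Suggestions per daily batch (default 10 each).
#' @param exploit_fraction Fraction of each batch drawn from frequent
#'   behaviors; the default 0.9 yields a fixed 9 exploit + 1 explore split.
#' @param frequent_min_count Minimum occurrences within the trailing 14-day
#'   window for a cluster to count as frequent (exploit-eligible).
#' @param small_change_walk_minutes Minutes of walking prescribed per
#'   stationary hour by small-change suggestions.
#' @param avoid_kcal_cutoff Named numeric: per-instance kcal above which a
#'   frequent meal cluster is framed as "avoid", per user goal.
#' @param rng_seed Integer seed for the explore draw.
#' @return A list of class `engine_config`.
#' @export
engine_config <- function(n_activity = 10,
                          n_food = 10,
                          exploit_fraction = 0.9,
                          frequent_min_count = 3,
                          small_change_walk_minutes = 3,
                          avoid_kcal_cutoff = c(
                            lose = 500, maintain = 700, gain = Inf
                          ),
                          rng_seed = 1) {
  stopifnot_scalar_number(n_activity, "n_activity", min = 1)
  stopifnot_scalar_number(n_food, "n_food", min = 1)
  stopifnot_scalar_number(exploit_fraction, "exploit_fraction")
  if (exploit_fraction <= 0 || exploit_fraction >= 1) {
    abort("`exploit_fraction` must lie strictly between 0 and 1.")
  }
  stopifnot_scalar_number(frequent_min_count, "frequent_min_count", min = 1)
  stopifnot_scalar_number(
    small_change_walk_minutes, "small_change_walk_minutes",
    min = 0, strict = TRUE
  )
  structure(
    list(
      n_activity = as.integer(n_activity), n_food = as.integer(n_food),
      exploit_fraction = exploit_fraction,
      frequent_min_count = frequent_min_count,
      small_change_walk_minutes = small_change_walk_minutes,
      avoid_kcal_cutoff = avoid_kcal_cutoff,
      rng_seed = as.integer(rng_seed)
    ),
    class = "engine_config"
  )
}

#' Metabolic-equivalent (MET) table
#'
#' METs express the energy cost of an activity as a multiple of resting
#' metabolism; calories burned are `MET x weight_kg x hours`. The default
#' table carries the four automatically recognized classes plus a few
#' manually loggable exercises.
#'
#' @param path Optional CSV with columns `label,met` overriding the default.
#' @return A tibble with columns `label` and `met`.
#' @examples
#' met_table()
#' @export
met_table <- function(path = NULL) {
  if (is.null(path)) {
    tbl <- tibble(
      label = c(
        "stationary", "walking", "running", "driving",
        "gym_workout", "cycling", "swimming", "yoga"
      ),
      met = c(1.3, 3.5, 8.0, 1.3, 6.0, 7.5, 6.0, 2.5)
    )
  } else {
    tbl <- readr::read_csv(
      path,
      col_types = readr::cols(
        label = readr::col_character(), met = readr::col_double()
      )
    )
  }
  if (any(tbl$met <= 0)) abort("All MET values must be > 0.")
  tbl
}

#' Read a food table
#'
#' The food table maps logged `food_id`s to names, calories per unit and
#' ingredient token sets (semicolon-separated). The bundled table is a small
#' synthetic stand-in for a full calorie database, sufficient for the
#' clustering and suggestion stages.
#'
#' @param path CSV path; defaults to the bundled synthetic table.
#' @return A tibble with columns `food_id`, `name`, `kcal_per_unit`,
#'   `category`, and list-column `ingredients`.
#' @examples
#' head(read_food_table())
#' @export
read_food_table <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "food_table_synthetic.csv", package = "habitr")
  if (!nzchar(path) || !file.exists(path)) {
    abort(sprintf("Food table not found: '%s'.", path))
  }
  tbl <- readr::read_csv(
    path,
    col_types = readr::cols(
      food_id = readr::col_character(),
      name = readr::col_character(),
      kcal_per_unit = readr::col_double(),
      category = readr::col_character(),
      ingredients = readr::col_character()
    )
  )
  tbl$ingredients <- strsplit(tbl$ingredients, ";", fixed = TRUE)
  tbl
}

#' Generic control-arm suggestion pool
#'
#' A pool of short prescriptive healthy-living suggestions used for the
#' control arm of simulated trials. The bundled pool holds 42 synthetic
#' placeholder entries.
#'
#' @param path CSV path with columns `id,category,text`; defaults to the
#'   bundled synthetic pool.
#' @return A tibble with columns `id`, `category`, `text`.
#' @export
generic_suggestion_pool <- function(path = NULL) {
  path <- path %||%
    system.file(
      "extdata", "generic_suggestions_synthetic.csv",
      package = "habitr"
    )
  if (!nzchar(path) || !file.exists(path)) {
    abort(sprintf("Suggestion pool not found: '%s'.", path))
  }
  readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_character(),
      category = readr::col_character(),
      text = readr::col_character()
    )
  )
}
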