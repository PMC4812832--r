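#' Simulate labeled accelerometer windows for the four activity classes
#'
#' Draws 1-second windows at `rate_hz` from class-conditional signal
#' models: per-axis Gaussian noise whose scale separates the classes
#' (stationary < driving < walking < running), plus a gait sinusoid on the
#' vertical axis for walking (2 Hz) and running (3 Hz) so the
#' zero-crossing-rate features carry periodicity information. Used to
#' train and evaluate the activity classifier.
#'
#' @param n_per_class Windows per class.
#' @param seed Integer seed.
#' @param rate_hz Sampling rate within each window.
#' @param window_s Window length, seconds.
#' @return Tibble of feature rows (see [extract_features()]) with a
#'   `label` column.
#' @examples
#' simulate_accel_windows(5, seed = 1)
#' @export
simulate_accel_windows <- function(n_per_class = 100, seed = 1,
                                   rate_hz = 20, window_s = 1) {
  n_s <- as.integer(rate_hz * window_s)
  with_seed(seed, {
    rows <- lapply(.activity_levels, function(lab) {
      lapply(seq_len(n_per_class), function(i) {
        w <- accel_samples(lab, n_s, rate_hz)
        f <- extract_features(w, sample_rate_hz = rate_hz)
        f$label <- lab
        f
      })
    })
    list_rbind(lapply(rows, list_rbind))
  })
}

# Class-conditional accelerometer model (g units). The gait sinusoid is
# only added when the sampling rate can represent it (>= 4x its
# frequency); 1 Hz life streams therefore use the pure-noise model.
accel_params <- function(label) {
  switch(label,
    stationary = list(sd = c(0.005, 0.005, 0.008), az0 = 1.00,
                      amp = 0, freq = 0),
    driving    = list(sd = c(0.030, 0.030, 0.045), az0 = 1.00,
                      amp = 0, freq = 0),
    walking    = list(sd = c(0.080, 0.080, 0.180), az0 = 1.00,
                      amp = 0.25, freq = 2),
    running    = list(sd = c(0.250, 0.250, 0.450), az0 = 1.05,
                      amp = 0.60, freq = 3),
    abort(sprintf("No accelerometer model for label '%s'.", label))
  )
}

accel_samples <- function(label, n, rate_hz) {
  p <- accel_params(label)
  az <- stats::rnorm(n, p$az0, p$sd[3])
  if (p$amp > 0 && rate_hz >= 4 * p$freq) {
    phase <- stats::runif(1, 0, 2 * pi)
    az <- az + p$amp * sin(2 * pi * p$freq * seq_len(n) / rate_hz + phase)
  }
  tibble(
    ax = stats::rnorm(n, 0, p$sd[1]),
    ay = stats::rnorm(n, 0, p$sd[2]),
    az = az
  )
}

#' Simulate one user's sensor stream, food log and ground truth
#'
#' Generates `config$days` days of routine behavior from a fixed day
#' template: stationary at home overnight; on commute days a morning walk
#' to the office along a user-specific jittered polyline, a stationary
#' office day and a driven trip home; on other days a stationary home
#' day; optional evening running loops; meals at fixed windows
#' (breakfast, lunch, dinner) drawn from a small per-user repertoire plus
#' Poisson snacks, all with lognormal calories. From week 2 (day 8)
#' onward a non-zero `intervention_effect` lengthens walks by
#' `1 + effect` and scales meal calories by `1 - effect`.
#'
#' All randomness comes from a stream derived from
#' `(config$seed, profile$user_id)`, so identical inputs give
#' byte-identical outputs and adding users never perturbs existing ones.
#'
#' @param profile A [user_profile()].
#' @param config A [scenario_config()].
#' @param sensors If `TRUE`, also generate the full 1 Hz labeled sensor
#'   stream (`timestamp, ax, ay, az, lat, lon` plus `true_label`);
#'   event-level ground truth is always produced.
#' @param traces If `TRUE`, attach a GPS trace to every ground-truth
#'   event (10 s sampling for moving events). Trial-statistics workloads
#'   can turn this off.
#' @param food_table Food lookup table used to build the repertoire.
#' @return A list of class `simulated_user` with elements `profile`,
#'   `config`, `ground_truth` (event tibble with true labels, place ids,
#'   trajectory ids and GPS traces), `food_log`, and `sensors` (tibble or
#'   `NULL`).
#' @examples
#' u <- simulate_user(user_profile("u1"), scenario_config(days = 2),
#'                    sensors = FALSE)
#' head(u$ground_truth)
#' @export
simulate_user <- function(profile, config, sensors = TRUE, traces = TRUE,
                          food_table = read_food_table()) {
  if (!inherits(profile, "user_profile")) {
    abort("`profile` must be a user_profile().")
  }
  if (!inherits(config, "scenario_config")) {
    abort("`config` must be a scenario_config().")
  }
  seed_u <- derive_seed(config$seed, profile$user_id)
  with_seed(seed_u, {
    origin <- list(lat = profile$home[["lat"]], lon = profile$home[["lon"]])
    home_xy <- c(0, 0)
    office_xy <- ll_to_xy(
      profile$office[["lat"]], profile$office[["lon"]], origin
    )[1, ]
    # user-fixed routes (drawn once -> repeated trajectories to recover)
    commute_route <- jittered_route(home_xy, office_xy, k = 12,
                                    jitter_sd = 40)
    gym_route <- loop_route(home_xy, radius_m = 350, k = 16)
    repertoire <- list(
      breakfast = sample(
        food_table$food_id[food_table$category == "breakfast"], 2
      ),
      main = sample(food_table$food_id[food_table$category == "main"], 4),
      snack = sample(food_table$food_id[food_table$category == "snack"], 3)
    )
    base_date <- as.POSIXct("2026-01-05 00:00:00", tz = "UTC")
    days <- config$days
    eff <- config$intervention_effect
    walk_day <- stats::runif(days) < config$routine_walks_per_week / 7
    gym_day <- stats::runif(days) < config$gym_visits_per_week / 7
    mult_w <- ifelse(seq_len(days) >= 8, 1 + eff, 1)
    mult_k <- ifelse(seq_len(days) >= 8, 1 - eff, 1)
    wdur_s <- round(1800 * exp(stats::rnorm(days, 0, 0.15)) * mult_w)
    rdur_s <- round(1500 * exp(stats::rnorm(days, 0, 0.15)))

    gt <- build_day_events(days, base_date, walk_day, gym_day, wdur_s,
                           rdur_s, profile$user_id)
    food <- build_meals(days, base_date, config, repertoire, food_table,
                        mult_k, profile$user_id)

    if (isTRUE(traces) || isTRUE(sensors)) {
      gt$trace <- event_traces(gt, commute_route, gym_route, home_xy,
                               office_xy, origin, config$gps_noise_sd)
    } else {
      gt$trace <- vector("list", nrow(gt))
    }
    sensors_tbl <- NULL
    if (isTRUE(sensors)) {
      sensors_tbl <- sensor_stream(gt, commute_route, gym_route, home_xy,
                                   office_xy, origin, config$gps_noise_sd)
    }
    structure(
      list(
        profile = profile, config = config,
        ground_truth = gt, food_log = food, sensors = sensors_tbl
      ),
      class = "simulated_user"
    )
  })
}

# Activity partition for all days at once: every second of every day
# carries exactly one label. Pure vector construction for speed.
build_day_events <- function(days, base_date, walk_day, gym_day, wdur_s,
                             rdur_s, user_id) {
  t_wake <- 7 * 3600 + 40 * 60
  t_leave <- 17 * 3600 + 30 * 60
  t_run <- 18 * 3600 + 30 * 60
  start <- end <- numeric(0)
  label <- place <- traj <- character(0)
  day_ix <- integer(0)
  for (d in seq_len(days)) {
    off <- (d - 1) * 86400
    if (walk_day[d]) {
      t_arr <- t_wake + wdur_s[d]
      s <- c(0, t_wake, t_arr, t_leave)
      e <- c(t_wake, t_arr, t_leave, t_leave + 1200)
      l <- c("stationary", "walking", "stationary", "driving")
      p <- c("home", NA, "office", NA)
      tr <- c(NA, "commute_am", NA, "drive_home")
      t_home <- t_leave + 1200
    } else {
      s <- 0
      e <- t_wake
      l <- "stationary"
      p <- "home"
      tr <- NA_character_
      t_home <- t_wake
    }
    if (gym_day[d]) {
      s <- c(s, t_home, t_run, t_run + rdur_s[d])
      e <- c(e, t_run, t_run + rdur_s[d], 86400)
      l <- c(l, "stationary", "running", "stationary")
      p <- c(p, "home", NA, "home")
      tr <- c(tr, NA, "gym_loop", NA)
    } else {
      s <- c(s, t_home)
      e <- c(e, 86400)
      l <- c(l, "stationary")
      p <- c(p, "home")
      tr <- c(tr, NA)
    }
    start <- c(start, off + s)
    end <- c(end, off + e)
    label <- c(label, l)
    place <- c(place, p)
    traj <- c(traj, tr)
    day_ix <- c(day_ix, rep(d, length(s)))
  }
  dur_min <- (end - start) / 60
  tibble(
    user_id = user_id,
    day = day_ix,
    start = base_date + start,
    end = base_date + end,
    kind = "activity",
    label = label,
    place_id = place,
    trajectory_id = traj,
    duration_min = dur_min
  )
}

lnorm_pars <- function(mean, sd) {
  if (mean <= 0) abort("Calorie mean must be > 0.")
  cv2 <- (sd / mean)^2
  list(meanlog = log(mean) - log(1 + cv2) / 2, sdlog = sqrt(log(1 + cv2)))
}

build_meals <- function(days, base_date, config, repertoire, food_table,
                        mult_k, user_id) {
  mp <- lnorm_pars(config$meal_kcal_mean, config$meal_kcal_sd)
  sp <- lnorm_pars(config$snack_kcal_mean, config$snack_kcal_sd)
  meal_at <- c(
    breakfast = 7 * 3600 + 25 * 60,
    lunch = 12 * 3600 + 30 * 60,
    dinner = 19 * 3600 + 5 * 60
  )
  d <- rep(seq_len(days), each = 3)
  meal <- rep(names(meal_at), times = days)
  fid <- ifelse(
    meal == "breakfast",
    sample(repertoire$breakfast, 3 * days, replace = TRUE),
    sample(repertoire$main, 3 * days, replace = TRUE)
  )
  kcal <- stats::rlnorm(3 * days, mp$meanlog, mp$sdlog) * mult_k[d]
  at <- (d - 1) * 86400 + unname(meal_at[meal])
  n_snack <- stats::rpois(days, config$snacks_per_day)
  tot <- sum(n_snack)
  if (tot > 0) {
    sd_day <- rep(seq_len(days), n_snack)
    s_at <- (sd_day - 1) * 86400 + round(stats::runif(tot, 10 * 3600,
                                                      17 * 3600))
    s_fid <- sample(repertoire$snack, tot, replace = TRUE)
    s_kcal <- stats::rlnorm(tot, sp$meanlog, sp$sdlog)
    d <- c(d, sd_day)
    meal <- c(meal, rep("snack", tot))
    fid <- c(fid, s_fid)
    kcal <- c(kcal, s_kcal)
    at <- c(at, s_at)
  }
  per_unit <- food_table$kcal_per_unit[match(fid, food_table$food_id)]
  ord <- order(at)
  tibble(
    user_id = user_id,
    timestamp = base_date + at[ord],
    food_id = fid[ord],
    quantity = round(kcal[ord] / per_unit[ord], 3),
    meal = meal[ord],
    day = d[ord]
  )
}

# Fixed per-user route: straight line with perpendicular jitter on the
# interior waypoints.
jittered_route <- function(from_xy, to_xy, k = 12, jitter_sd = 40) {
  t <- seq(0, 1, length.out = k)
  x <- from_xy[1] + t * (to_xy[1] - from_xy[1])
  y <- from_xy[2] + t * (to_xy[2] - from_xy[2])
  dx <- to_xy[1] - from_xy[1]
  dy <- to_xy[2] - from_xy[2]
  len <- sqrt(dx^2 + dy^2)
  nx <- -dy / len
  ny <- dx / len
  off <- c(0, stats::rnorm(k - 2, 0, jitter_sd), 0)
  cbind(x = x + off * nx, y = y + off * ny)
}

loop_route <- function(anchor_xy, radius_m = 350, k = 16) {
  center <- anchor_xy + c(stats::runif(1, 150, 400),
                          stats::runif(1, 150, 400))
  ang <- seq(0, 2 * pi, length.out = k)
  r <- radius_m * (1 + stats::rnorm(k, 0, 0.05))
  pts <- cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))
  rbind(anchor_xy, pts, anchor_xy)
}

# Positions along a route at given fractions of its arc length.
route_positions <- function(route, frac) {
  seg <- sqrt(diff(route[, 1])^2 + diff(route[, 2])^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- frac * total
  x <- stats::approx(cum, route[, 1], xout = s, ties = "ordered")$y
  y <- stats::approx(cum, route[, 2], xout = s, ties = "ordered")$y
  cbind(x, y)
}

event_route <- function(traj_id, commute_route, gym_route) {
  switch(traj_id,
    commute_am = commute_route,
    drive_home = commute_route[rev(seq_len(nrow(commute_route))), ],
    gym_loop = gym_route,
    NULL
  )
}

# GPS traces for ground-truth events: moving events sampled every 10 s
# along their route, stationary events as noisy points at their anchor.
event_traces <- function(gt, commute_route, gym_route, home_xy, office_xy,
                         origin, noise_sd) {
  lapply(seq_len(nrow(gt)), function(i) {
    dur_s <- as.numeric(gt$end[i]) - as.numeric(gt$start[i])
    if (!is.na(gt$trajectory_id[i])) {
      n <- max(2L, as.integer(dur_s / 10))
      xy <- route_positions(
        event_route(gt$trajectory_id[i], commute_route, gym_route),
        seq(0, 1, length.out = n)
      )
    } else {
      n <- 20L
      anchor <- if (identical(gt$place_id[i], "office")) {
        office_xy
      } else {
        home_xy
      }
      xy <- cbind(rep(anchor[1], n), rep(anchor[2], n))
    }
    xy <- xy + matrix(stats::rnorm(2 * n, 0, noise_sd), ncol = 2)
    as_tibble(as.data.frame(xy_to_ll(xy, origin)))
  })
}

# Full 1 Hz labeled sensor stream covering every second of every day.
sensor_stream <- function(gt, commute_route, gym_route, home_xy, office_xy,
                          origin, noise_sd) {
  parts <- lapply(seq_len(nrow(gt)), function(i) {
    dur_s <- as.integer(as.numeric(gt$end[i]) - as.numeric(gt$start[i]))
    if (dur_s <= 0) {
      return(NULL)
    }
    acc <- accel_samples(gt$label[i], dur_s, rate_hz = 1)
    if (!is.na(gt$trajectory_id[i])) {
      xy <- route_positions(
        event_route(gt$trajectory_id[i], commute_route, gym_route),
        seq(0, 1, length.out = dur_s)
      )
    } else {
      anchor <- if (identical(gt$place_id[i], "office")) {
        office_xy
      } else {
        home_xy
      }
      xy <- cbind(rep(anchor[1], dur_s), rep(anchor[2], dur_s))
    }
    xy <- xy + matrix(stats::rnorm(2 * dur_s, 0, noise_sd), ncol = 2)
    ll <- xy_to_ll(xy, origin)
    tibble(
      timestamp = gt$start[i] + seq_len(dur_s) - 1L,
      ax = acc$ax, ay = acc$ay, az = acc$az,
      lat = ll[, 1], lon = ll[, 2],
      true_label = gt$label[i]
    )
  })
  list_rbind(parts)
}

#' Simulate a two-arm behavior-change trial
#'
#' Builds `n_experimental + n_control` users with staggered home/office
#' locations. Experimental users receive `config$intervention_effect`
#' (longer walks, lower meal calories from week 2 onward); control users
#' run the same scenario with the effect set to zero. Each user's random
#' stream derives from `(config$seed, user_id)`.
#'
#' @param n_experimental,n_control Arm sizes (>= 1).
#' @param config A [scenario_config()]; `days` should span 3 weeks for
#'   the trend analysis.
#' @param sensors,traces Passed to [simulate_user()]; both off by default
#'   because trial statistics operate on event-level logs.
#' @param food_table Food lookup table.
#' @return A list of class `trial` with `design` (tibble `user_id`,
#'   `arm`, `weight_kg`) and `users` (named list of `simulated_user`).
#' @examples
#' tr <- simulate_trial(2, 2, scenario_config(days = 21, seed = 1))
#' tr$design
#' @export
simulate_trial <- function(n_experimental, n_control, config,
                           sensors = FALSE, traces = FALSE,
                           food_table = read_food_table()) {
  if (n_experimental < 1 || n_control < 1) {
    abort("Both arms need at least 1 user.")
  }
  ids <- c(
    sprintf("e%02d", seq_len(n_experimental)),
    sprintf("c%02d", seq_len(n_control))
  )
  arms <- rep(c("experimental", "control"), c(n_experimental, n_control))
  cfg_ctrl <- config
  cfg_ctrl$intervention_effect <- 0
  users <- lapply(seq_along(ids), function(i) {
    prof <- user_profile(
      ids[i],
      weight_kg = 60 + 2 * (i %% 7),
      home = c(lat = 42.4440 + 0.01 * (i - 1), lon = -76.5019),
      office = c(lat = 42.4534 + 0.01 * (i - 1), lon = -76.4735)
    )
    cfg <- if (arms[i] == "experimental") config else cfg_ctrl
    simulate_user(prof, cfg, sensors = sensors, traces = traces,
                  food_table = food_table)
  })
  names(users) <- ids
  structure(
    list(
      design = tibble(
        user_id = ids, arm = arms,
        weight_kg = map_dbl(users, ~ .x$profile$weight_kg)
      ),
      users = users,
      config = config
    ),
    class = "trial"
  )
}

#' Convert a simulated user's ground truth into a life log
#'
#' Maps ground-truth events and the food log straight into the `lifelog`
#' schema (food calories from the table, activity calories from METS),
#' for feeding clustering, suggestions, and trial statistics with
#' known-truth inputs.
#'
#' @param user A `simulated_user`.
#' @param food_table Food lookup table.
#' @param mets MET table.
#' @return A `lifelog` tibble with `user_id` carried along.
#' @export
as_lifelog <- function(user, food_table = read_food_table(),
                       mets = met_table()) {
  gt <- user$ground_truth
  fl <- user$food_log
  n_a <- nrow(gt)
  n_f <- nrow(fl)
  start <- c(gt$start, fl$timestamp)
  out <- tibble(
    start = start,
    end = c(gt$end, fl$timestamp + 60),
    kind = c(gt$kind, rep("food", n_f)),
    label = c(gt$label, fl$food_id),
    duration_min = c(gt$duration_min, rep(1, n_f)),
    kcal = c(
      activity_kcal(gt$label, gt$duration_min, user$profile$weight_kg,
                    mets),
      food_kcal(fl$food_id, fl$quantity, food_table)
    ),
    trace = c(gt$trace %||% vector("list", n_a), vector("list", n_f)),
    user_id = c(gt$user_id, fl$user_id)
  )
  as_lifelog_tbl(out[order(start), ])
}
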