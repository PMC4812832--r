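test_that("stationary events within 150 m share a cluster; far ones do
           not", {
  # 0.001 deg latitude at the equator is about 111 m < 150 m
  ev <- make_events(rep("stationary", 3), c(30, 30, 30), gaps = 10)
  ev$trace <- list(
    tibble::tibble(lat = 0, lon = 0),
    tibble::tibble(lat = 0.001, lon = 0),
    tibble::tibble(lat = 0.05, lon = 0) # ~5.6 km away
  )
  cl <- cluster_stationary(ev)
  expect_equal(nrow(cl), 2)
  grp <- rep(NA_integer_, 3)
  for (i in seq_len(nrow(cl))) grp[cl$member_ids[[i]]] <- i
  expect_equal(grp[1], grp[2])
  expect_false(grp[1] == grp[3])
})

test_that("single linkage chains pairs within the radius and events
           without locations go to the unlocated cluster", {
  # chain: a-b 120 m, b-c 120 m, a-c 240 m -> all one cluster
  lat <- c(0, 0.00108, 0.00216)
  ev <- make_events(rep("stationary", 4), rep(10, 4), gaps = 5)
  ev$trace <- c(
    lapply(lat, function(l) tibble::tibble(lat = l, lon = 0)),
    list(tibble::tibble(lat = numeric(), lon = numeric()))
  )
  cl <- cluster_stationary(ev)
  expect_setequal(cl$cluster_id, c("stat_001", "unlocated"))
  located <- cl[cl$cluster_id != "unlocated", ]
  expect_equal(located$n_members, 3)
  # direct pairwise assertion of the linkage property
  pts <- do.call(rbind, lapply(ev$trace[1:3], as.data.frame))
  d <- geosphere::distHaversine(pts[c(1, 2), 2:1], pts[c(2, 3), 2:1])
  expect_true(all(d <= 150))
})

test_that("trajectory resampling preserves endpoints, spacing and length", {
  # straight segment ~310 m along a meridian
  tr <- straight_trace(0, 0, 0.0028, 0, n = 7)
  can <- resample_trajectory(tr, m = 32)
  expect_equal(nrow(can), 32)
  expect_equal(can$lat[1], 0)
  expect_equal(can$lat[32], 0.0028)
  seg <- geosphere::distHaversine(
    cbind(can$lon[-32], can$lat[-32]), cbind(can$lon[-1], can$lat[-1])
  )
  expect_lt(diff(range(seg)) / mean(seg), 0.01) # equidistant within 1%
  expect_equal(attr(can, "path_length_m"),
               geosphere::distHaversine(c(0, 0), c(0, 0.0028)),
               tolerance = 0.01)
  # fixed point: resampling a canonical trajectory changes nothing
  again <- resample_trajectory(can, m = 32)
  expect_equal(again$lat, can$lat, tolerance = 1e-10)
  expect_equal(again$lon, can$lon, tolerance = 1e-10)
  expect_error(
    resample_trajectory(tibble::tibble(lat = c(1, 1), lon = c(2, 2))),
    "distinct"
  )
})

test_that("path length survives resampling on a 1 km zig-zag within 1%", {
  lat <- seq(0, 0.0085, length.out = 6) # ~190 m legs, 4 corners
  lon <- rep(c(0, 0.0004), 3)
  tr <- tibble::tibble(lat = lat, lon = lon)
  poly_len <- sum(geosphere::distHaversine(
    cbind(lon[-6], lat[-6]), cbind(lon[-1], lat[-1])
  ))
  expect_gt(poly_len, 900) # ~1 km path
  can <- resample_trajectory(tr, m = 32)
  expect_equal(attr(can, "path_length_m"), poly_len,
               tolerance = 0.01)
})

test_that("trajectory distance: zero iff identical, symmetric, translates
           rigidly", {
  a <- resample_trajectory(straight_trace(0, 0, 0.01, 0.01), m = 32)
  expect_equal(trajectory_distance(a, a), 0)
  # translate ~1000 m north: every point moves equally
  b <- a
  b$lat <- b$lat + 1000 / 111194.9
  expect_equal(trajectory_distance(a, b), 1000, tolerance = 0.01)
  set.seed(1)
  c_ <- resample_trajectory(
    tibble::tibble(lat = cumsum(runif(8, 1e-4, 1e-3)),
                   lon = cumsum(runif(8, 1e-4, 1e-3))),
    m = 32
  )
  expect_equal(trajectory_distance(a, c_), trajectory_distance(c_, a))
  expect_gt(trajectory_distance(a, c_), 0)
  expect_error(
    trajectory_distance(a, resample_trajectory(straight_trace(0, 0, 1, 1),
                                               m = 16)),
    "same number"
  )
})

test_that("leader clustering groups noisy repeats and separates
           directions", {
  set.seed(11)
  base <- straight_trace(42.44, -76.50, 42.45, -76.49, n = 40)
  noisy <- function(tr) {
    tr$lat <- tr$lat + rnorm(nrow(tr), 0, 20 / 111194.9)
    tr$lon <- tr$lon + rnorm(nrow(tr), 0, 20 / 81000)
    tr
  }
  ev <- make_events(rep("walking", 17), rep(30, 17), gaps = 60)
  ev$trace <- c(
    lapply(1:15, function(i) noisy(base)), # 15 noisy repeats
    list(noisy(base[rev(seq_len(nrow(base))), ])), # the reverse direction
    list(noisy(straight_trace(42.40, -76.40, 42.39, -76.41, n = 40)))
  )
  cl <- cluster_trajectories(ev)
  expect_equal(nrow(cl), 3)
  expect_equal(sort(cl$n_members, decreasing = TRUE)[1], 15)
  expect_equal(sum(cl$n_members), 17) # partition property
  # commute A->B vs B->A live in different clusters
  grp <- rep(NA_integer_, 17)
  for (i in seq_len(nrow(cl))) grp[cl$member_ids[[i]]] <- i
  expect_false(grp[1] == grp[16])
})

test_that("food clustering follows ingredient Jaccard with a 0.5
           threshold and never mixes meals with snacks", {
  ft <- tibble::tibble(
    food_id = c("B1", "B2", "S1", "S2"),
    name = c("cheeseburger", "lettuce burger", "apple", "kale chips"),
    kcal_per_unit = c(550, 500, 80, 90),
    category = c("main", "main", "snack", "snack"),
    ingredients = list(
      c("bun", "beef patty", "cheese"),
      c("bun", "beef patty", "lettuce"), # Jaccard 2/4 = 0.5 with B1
      "apple",
      "kale" # disjoint from apple
    )
  )
  # burgers at lunch (meal window); light snacks mid-afternoon
  at <- ts0() + c(12.2, 12.7, 15, 16) * 3600
  ev <- make_events(rep("stationary", 4), rep(1, 4))
  ev$start <- at
  ev$end <- at + 60
  ev$kind <- "food"
  ev$label <- c("B1", "B2", "S1", "S2")
  ev$kcal <- c(550, 500, 80, 90)
  cl <- cluster_foods(ev, ft)
  burgers <- cl[cl$cluster_type == "meal", ]
  expect_equal(nrow(burgers), 1) # one burger cluster at exactly 0.5
  expect_equal(burgers$n_members, 2)
  snacks <- cl[cl$cluster_type == "snack", ]
  expect_equal(nrow(snacks), 2) # disjoint ingredient sets stay apart
  expect_error(
    cluster_foods(dplyr::mutate(ev, label = "nope"), ft),
    "nope"
  )
})

test_that("identical food items always share a cluster", {
  ft <- read_food_table()
  ev <- make_events(rep("stationary", 3), rep(1, 3), gaps = 200)
  ev$kind <- "food"
  ev$label <- rep("F101", 3)
  ev$kcal <- rep(550, 3)
  cl <- cluster_foods(ev, ft)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_members, 3)
})

test_that("meal/snack rule uses time windows and the calorie cutoff", {
  noon <- ts0() + 12.5 * 3600
  late <- ts0() + 15 * 3600
  expect_true(is_meal(noon, 100)) # in window
  expect_false(is_meal(late, 100)) # out of window, small
  expect_true(is_meal(late, 400)) # out of window but >= 250 kcal
})

test_that("clusters recover planted commutes on a simulated user at
           20 m GPS noise", {
  skip_if_not_installed("mclust")
  u <- simulate_user(
    user_profile("traj"),
    scenario_config(days = 21, seed = 7, gps_noise_sd = 20,
                    gym_visits_per_week = 2),
    sensors = FALSE
  )
  ll <- as_lifelog(u)
  cl <- cluster_lifelog(ll, read_food_table())
  # partition: every eligible event in exactly one cluster
  eligible <- which(
    (ll$kind == "activity" &
       ll$label %in% c("stationary", "walking", "running")) |
      ll$kind == "food"
  )
  counts <- integer(nrow(ll))
  for (i in seq_len(nrow(cl))) {
    counts[cl$member_ids[[i]]] <- counts[cl$member_ids[[i]]] + 1
  }
  expect_true(all(counts[eligible] == 1))
  # frequency equals member count within the trailing window
  expect_true(all(cl$frequency <= cl$n_members))
  # planted trajectory recovery
  traj_rows <- which(ll$kind == "activity" &
                       ll$label %in% c("walking", "running"))
  truth <- u$ground_truth$trajectory_id[
    u$ground_truth$label %in% c("walking", "running")
  ]
  found <- rep(NA_integer_, nrow(ll))
  tcl <- cl[cl$cluster_type == "trajectory", ]
  for (i in seq_len(nrow(tcl))) found[tcl$member_ids[[i]]] <- i
  ari <- mclust::adjustedRandIndex(found[traj_rows], truth)
  expect_gte(ari, 0.9)
})
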