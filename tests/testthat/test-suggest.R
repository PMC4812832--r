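test_that("frequent moderate walks outrank rare intense gym sessions", {
  # 30-min walk at 3.5 MET, 70 kg -> 122.5 kcal, 5x/week = 612.5
  # 60-min gym at 6 MET -> 420 kcal, 1x/week = 420
  cl <- tibble::tibble(
    cluster_id = c("walk", "gym"),
    cluster_type = c("trajectory", "manual_exercise_type"),
    frequency = c(10, 2), # per 14 days -> 5 and 1 per week
    per_instance_kcal = c(3.5 * 70 * 0.5, 6 * 70),
    per_instance_duration = c(30, 60),
    window_days = 14
  )
  s <- score_activity_cluster(cl)
  expect_equal(s, c(612.5, 420))
  expect_gt(s[1], s[2])
  # linearity in frequency; zero frequency scores zero
  cl2 <- dplyr::mutate(cl, frequency = frequency * 2)
  expect_equal(score_activity_cluster(cl2), 2 * s)
  cl0 <- dplyr::mutate(cl, frequency = 0)
  expect_equal(score_activity_cluster(cl0), c(0, 0))
  expect_error(
    score_activity_cluster(dplyr::mutate(cl, cluster_type = "stationary_place")),
    "small_change"
  )
})

test_that("small-change suggestions prescribe the configured walk and
           follow the METS formula", {
  # 25 one-hour episodes per week at 70 kg
  cl <- tibble::tibble(
    cluster_id = "office",
    cluster_type = "stationary_place",
    frequency = 50, # per 14 days -> 25/week
    per_instance_duration = 60,
    rep_lat = 42.45, rep_lon = -76.47,
    window_days = 14
  )
  s <- small_change_for_stationary(cl, weight_kg = 70)
  expect_equal(s$walk_minutes, 3)
  expect_equal(s$kcal_per_instance, 12.25) # 3.5 x 70 x 0.05
  expect_equal(s$projected_weekly_kcal, 25 * 12.25)
  # outranks a once-a-week 245-kcal gym visit
  expect_gt(s$projected_weekly_kcal, 245)
  # zero stationary hours project zero
  s0 <- small_change_for_stationary(dplyr::mutate(cl, frequency = 0), 70)
  expect_equal(s0$projected_weekly_kcal, 0)
})

test_that("exploit/explore partition uses the frequency threshold and
           never proposes never-done behaviors", {
  cl <- make_clusters(3, 2)
  cl$frequency <- c(5, 4, 3, 2, 0)
  p <- partition_exploit_explore(cl, engine_config())
  expect_equal(p$frequent$cluster_id, c("c001", "c002", "c003"))
  expect_equal(p$infrequent$cluster_id, "c004") # frequency-0 dropped
  # all frequency >= threshold -> empty explore pool
  all_freq <- dplyr::mutate(cl, frequency = 5)
  expect_equal(nrow(partition_exploit_explore(all_freq)$infrequent), 0)
  # crossing the threshold migrates explore -> exploit
  cl$frequency[4] <- 3
  p2 <- partition_exploit_explore(cl, engine_config())
  expect_true("c004" %in% p2$frequent$cluster_id)
  expect_false("c004" %in% p2$infrequent$cluster_id)
})

test_that("daily batches hold exactly 9 exploit + 1 explore with a
           non-empty explore pool", {
  cl <- make_clusters(15, 4)
  prof <- user_profile("u", 70)
  b <- generate_daily_batch(cl, "activity", prof, engine_config(),
                            date = "2026-02-01")
  expect_equal(nrow(b), 10)
  expect_equal(b$rank, 1:10)
  expect_equal(sum(b$arm == "explore"), 1)
  expect_equal(sum(b$arm != "explore"), 9)
  # determinism under the same seed/date
  b2 <- generate_daily_batch(cl, "activity", prof, engine_config(),
                             date = "2026-02-01")
  expect_identical(b, b2)
  # explore candidates satisfy the calorie-direction filter
  med <- median(cl$per_instance_kcal)
  expl <- b[b$arm == "explore", ]
  expect_gt(expl$per_instance_kcal, med)
})

test_that("an empty explore pool backfills from exploit", {
  cl <- make_clusters(15, 0)
  b <- generate_daily_batch(cl, "activity", user_profile("u"),
                            engine_config(), date = "2026-02-01")
  expect_equal(nrow(b), 10)
  expect_equal(sum(b$arm == "explore"), 0)
})

test_that("scarce candidates emit as many suggestions as exist", {
  cl <- make_clusters(4, 0)
  expect_message(
    b <- generate_daily_batch(cl, "activity", user_profile("u"),
                              engine_config(), date = "2026-02-01"),
    "4 of 10"
  )
  expect_equal(nrow(b), 4)
})

test_that("exploit ranking matches a brute-force sort oracle and is
           monotone in frequency", {
  set.seed(21)
  cl <- make_clusters(12, 0, kcal = sample(100:900, 12))
  cl$frequency <- sample(3:9, 12, replace = TRUE)
  b <- generate_daily_batch(cl, "activity", user_profile("u", 70),
                            engine_config(), date = "2026-02-02")
  score <- cl$frequency / 14 * 7 * cl$per_instance_kcal
  oracle <- cl$cluster_id[order(-score)][1:9]
  expect_equal(b$target_cluster_id[1:9], oracle)
  # raising a cluster's frequency never lowers its rank
  for (target in cl$cluster_id[c(3, 8)]) {
    cl2 <- cl
    cl2$frequency[cl2$cluster_id == target] <-
      cl2$frequency[cl2$cluster_id == target] + 3
    b2 <- generate_daily_batch(cl2, "activity", user_profile("u", 70),
                               engine_config(), date = "2026-02-02")
    r1 <- match(target, b$target_cluster_id)
    r2 <- match(target, b2$target_cluster_id)
    expect_lte(r2, r1)
  }
})

test_that("food batches exploit frequent low-calorie clusters in
           ascending order and keep avoid items out of the slots", {
  cl <- make_clusters(12, 3, type = "meal",
                      kcal = c(seq(200, 750, length.out = 12),
                               150, 160, 900))
  prof <- user_profile("u", goal = "maintain") # avoid cutoff 700
  b <- generate_daily_batch(cl, "food", prof, engine_config(),
                            date = "2026-02-01")
  expect_equal(nrow(b), 10)
  ex <- b[b$arm == "exploit", ]
  expect_true(all(diff(ex$per_instance_kcal) >= 0)) # ascending kcal
  expect_true(all(ex$per_instance_kcal <= 700))
  expl <- b[b$arm == "explore", ]
  expect_equal(nrow(expl), 1)
  expect_lt(expl$per_instance_kcal, median(b$per_instance_kcal))
  # the frequent 750-kcal cluster shows up as an avoid suggestion
  av <- food_avoid_suggestions(cl, prof)
  expect_true(any(av$per_instance_kcal > 700))
  expect_false(any(av$target_cluster_id %in% ex$target_cluster_id))
})

test_that("generic control suggestions sample uniformly without
           replacement", {
  pool <- generic_suggestion_pool()
  expect_equal(nrow(pool), 42)
  all_of_them <- draw_generic_suggestions(pool, nrow(pool), seed = 4)
  expect_setequal(all_of_them$id, pool$id)
  # chi-square sanity check of single-draw uniformity
  draws <- vapply(1:800, function(s) {
    draw_generic_suggestions(pool, 1, seed = s)$id
  }, character(1))
  counts <- table(factor(draws, levels = pool$id))
  chi <- sum((counts - 800 / 42)^2 / (800 / 42))
  # df = 41; 99.9th percentile ~ 74
  expect_lt(chi, qchisq(0.999, df = 41))
})
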