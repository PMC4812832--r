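test_that("minute aggregation takes the majority and honors the tie rules", {
  # pure minute
  s <- make_seconds("walking", each = 60)
  expect_equal(aggregate_minute(s)$label, "walking")
  # 31 vs 29 majority
  s <- tibble::tibble(
    timestamp = ts0() + 0:59,
    label = rep(c("walking", "stationary"), c(31, 29))
  )
  expect_equal(aggregate_minute(s)$label, "walking")
  # 30/30 tie after a stationary minute -> stationary (continuity)
  s2 <- dplyr::bind_rows(
    make_seconds("stationary", each = 60),
    tibble::tibble(
      timestamp = ts0() + 60 + 0:59,
      label = rep(c("walking", "stationary"), each = 30)
    )
  )
  expect_equal(aggregate_minute(s2)$label, c("stationary", "stationary"))
  # tie with no previous minute -> fixed class order
  s3 <- tibble::tibble(
    timestamp = ts0() + 0:59,
    label = rep(c("running", "walking"), each = 30)
  )
  expect_equal(aggregate_minute(s3)$label, "walking")
  expect_equal(nrow(aggregate_minute(tibble::tibble(
    timestamp = as.POSIXct(character(), tz = "UTC"), label = character()
  ))), 0)
})

test_that("contiguous same-label minutes merge to one event of summed
           duration", {
  m <- make_minutes(rep("stationary", 50))
  ev <- merge_contiguous(m)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_min, 50)
  expect_equal(as.numeric(ev$end - ev$start, units = "mins"), 50)

  # alternating labels never merge
  alt <- make_minutes(rep(c("walking", "stationary"), 10))
  expect_equal(nrow(merge_contiguous(alt)), 20)

  # a gap in the minute sequence breaks a run
  gap <- make_minutes(rep("walking", 4))
  gap$minute[3:4] <- gap$minute[3:4] + 600
  expect_equal(nrow(merge_contiguous(gap)), 2)
})

test_that("merge_contiguous is idempotent and conserves labeled minutes", {
  set.seed(42)
  labs <- sample(c("stationary", "walking", "driving"), 300, replace = TRUE,
                 prob = c(0.7, 0.2, 0.1))
  m <- make_minutes(labs)
  ev <- merge_contiguous(m)
  expect_equal(sum(ev$duration_min), 300) # conservation
  # re-merge via expansion back to minutes
  back <- make_minutes(rep(ev$label, ev$duration_min))
  expect_equal(merge_contiguous(back)$label, ev$label)
  expect_equal(merge_contiguous(back)$duration_min, ev$duration_min)
  # sorted, non-overlapping
  expect_true(all(diff(as.numeric(ev$start)) > 0))
  expect_true(all(as.numeric(ev$start[-1]) >= as.numeric(ev$end[-nrow(ev)])))
})

test_that("short heterogeneous chains collapse into one mixed event", {
  # walk 5 / wait 4 / drive 10 / walk 3, no gaps -> one commute
  ev <- make_events(c("walking", "stationary", "driving", "walking"),
                    c(5, 4, 10, 3))
  mx <- build_mixed_events(ev)
  expect_equal(nrow(mx), 1)
  expect_equal(mx$kind, "mixed")
  expect_equal(mx$duration_min, 22)
  expect_equal(nrow(mx$constituents[[1]]), 4)
  expect_equal(mx$end - mx$start, ev$end[4] - ev$start[1])
})

test_that("long events, long gaps and homogeneous chains are left alone", {
  # single 50-min stationary event unchanged
  ev <- make_events("stationary", 50)
  expect_equal(build_mixed_events(ev)$label, "stationary")
  # 20-min gap between two short walks: two events survive
  ev2 <- make_events(c("walking", "walking"), c(5, 5), gaps = c(0, 20))
  expect_equal(nrow(build_mixed_events(ev2)), 2)
  # >= 15 min constituents are never absorbed
  ev3 <- make_events(c("walking", "stationary", "walking"), c(5, 20, 5))
  out <- build_mixed_events(ev3)
  expect_equal(nrow(out), 3)
  expect_false(any(out$kind == "mixed"))
  # same-label chain is not "mixed"
  ev4 <- make_events(c("walking", "walking"), c(5, 5), gaps = c(0, 2))
  expect_false(any(build_mixed_events(ev4)$kind == "mixed"))
})

test_that("build_mixed_events is idempotent", {
  ev <- make_events(
    c("walking", "stationary", "driving", "walking", "stationary",
      "walking", "running"),
    c(5, 4, 10, 3, 40, 6, 7), gaps = c(0, 0, 0, 0, 1, 2, 1)
  )
  once <- build_mixed_events(ev)
  twice <- build_mixed_events(once)
  expect_equal(as.data.frame(twice), as.data.frame(once))
})

test_that("assembly interleaves food chronologically and computes kcal", {
  ev <- make_events(c("stationary", "walking"), c(60, 30))
  food <- tibble::tibble(
    timestamp = ts0() + 45 * 60, food_id = "F201", quantity = 2
  )
  ll <- assemble_lifelog(ev, food, profile = user_profile("u", 70))
  expect_equal(ll$kind, c("activity", "food", "activity"))
  expect_equal(ll$kcal[2], 160) # 80 kcal/unit x 2
  expect_equal(ll$kcal[3], 3.5 * 70 * 0.5) # METS walking 30 min
  # empty food log: unchanged event set
  ll2 <- assemble_lifelog(ev, NULL, profile = user_profile("u", 70))
  expect_equal(nrow(ll2), 2)
})

test_that("direct label calories override the food table", {
  ev <- make_events("stationary", 10)
  food <- tibble::tibble(
    timestamp = ts0() + 60, food_id = "F201", quantity = 1,
    label_kcal = c(180)
  )
  ll <- assemble_lifelog(ev, food, profile = user_profile("u", 70))
  expect_equal(ll$kcal[ll$kind == "food"], 180)
})

test_that("manual entries win over overlapping automatic events", {
  ev <- make_events("stationary", 120) # 00:00 - 02:00
  man <- tibble::tibble(
    start = ts0() + 30 * 60, end = ts0() + 60 * 60, activity = "cycling"
  )
  ll <- assemble_lifelog(ev, NULL, man, profile = user_profile("u", 70))
  expect_equal(ll$kind, c("activity", "manual_exercise", "activity"))
  expect_equal(ll$duration_min, c(30, 30, 60))
  expect_equal(ll$label[2], "manual:cycling")
  expect_equal(ll$kcal[2], 7.5 * 70 * 0.5) # cycling MET 7.5
  # total non-overlap preserved
  expect_true(all(as.numeric(ll$start[-1]) >= as.numeric(ll$end[-3])))
})

test_that("mixed events burn the duration-weighted sum of their
           constituents", {
  ev <- make_events(c("walking", "driving"), c(10, 10))
  mx <- build_mixed_events(ev)
  ll <- assemble_lifelog(mx, NULL, profile = user_profile("u", 60))
  expected <- 3.5 * 60 * 10 / 60 + 1.3 * 60 * 10 / 60
  expect_equal(ll$kcal, expected)
})
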