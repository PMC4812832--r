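# Shared fixture builders. Everything is generated in code; no files.

ts0 <- function() as.POSIXct("2026-01-05 00:00:00", tz = "UTC")

# A per-second label stream: one label per entry of `labels`, each
# repeated for `each` seconds.
make_seconds <- function(labels, each = 60, start = ts0()) {
  lab <- rep(labels, each = each)
  tibble::tibble(
    timestamp = start + seq_along(lab) - 1,
    label = lab
  )
}

# Minute-level labels directly.
make_minutes <- function(labels, start = ts0()) {
  tibble::tibble(
    minute = start + 60 * (seq_along(labels) - 1),
    label = labels
  )
}

# Activity events with given labels/durations (minutes) and gaps
# (minutes, before each event; first gap is offset from start).
make_events <- function(labels, durations, gaps = 0, start = ts0()) {
  gaps <- rep_len(gaps, length(labels))
  starts <- ends <- as.POSIXct(numeric(length(labels)),
                               origin = "1970-01-01", tz = "UTC")
  t <- start
  for (i in seq_along(labels)) {
    t <- t + gaps[i] * 60
    starts[i] <- t
    t <- t + durations[i] * 60
    ends[i] <- t
  }
  ll <- tibble::tibble(
    start = starts, end = ends, kind = "activity",
    label = labels, duration_min = durations
  )
  class(ll) <- c("lifelog", class(ll))
  ll
}

# Synthetic behavior clusters for suggestion-engine tests.
make_clusters <- function(n_frequent = 15, n_infrequent = 4,
                          type = "trajectory",
                          freq_frequent = 5, freq_infrequent = 1,
                          kcal = NULL) {
  n <- n_frequent + n_infrequent
  if (is.null(kcal)) kcal <- seq(100, 100 + 10 * (n - 1), by = 10)
  tibble::tibble(
    cluster_id = sprintf("c%03d", seq_len(n)),
    cluster_type = type,
    label = if (type == "trajectory") "walking" else NA_character_,
    n_members = rep(c(freq_frequent, freq_infrequent),
                    c(n_frequent, n_infrequent)),
    member_ids = lapply(seq_len(n), function(i) i),
    frequency = rep(c(freq_frequent, freq_infrequent),
                    c(n_frequent, n_infrequent)),
    per_instance_kcal = kcal,
    per_instance_duration = rep(30, n),
    rep_lat = 42.44, rep_lon = -76.50,
    rep_name = sprintf("item %d", seq_len(n)),
    window_days = 14
  )
}

# A straight trace between two lat/lon points with n vertices.
straight_trace <- function(lat1, lon1, lat2, lon2, n = 10) {
  tibble::tibble(
    lat = seq(lat1, lat2, length.out = n),
    lon = seq(lon1, lon2, length.out = n)
  )
}

# Quadratic-discriminant oracle for k = 1 Gaussian class models with
# diagonal covariance: independent route used to check classify().
qda_oracle <- function(features, labels, newdata, priors = NULL) {
  cols <- grep("_(mean|var|zcr)$", names(features), value = TRUE)
  classes <- sort(unique(labels))
  if (is.null(priors)) {
    priors <- as.numeric(table(labels)[classes] / length(labels))
  }
  x <- as.matrix(newdata[, cols])
  scores <- sapply(seq_along(classes), function(i) {
    xi <- as.matrix(features[labels == classes[i], cols])
    mu <- colMeans(xi)
    v <- pmax(apply(xi, 2, function(c) mean((c - mean(c))^2)), 1e-12)
    log(priors[i]) - 0.5 * sum(log(2 * pi * v)) -
      0.5 * colSums((t(x) - mu)^2 / v)
  })
  scores <- matrix(scores, nrow = nrow(x))
  classes[apply(scores, 1, which.max)]
}
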