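#' Cluster stationary events by place
#'
#' Single-linkage grouping of stationary-event locations under haversine
#' distance with a 150 m threshold, the scale at which indoor localization
#' is considered accurate: any two events within `radius_m` of each other
#' end up in the same cluster. An event's location is the coordinate-wise
#' median of its GPS trace; events without a location fall into a special
#' `"unlocated"` cluster that is excluded from suggestions.
#'
#' @param events `lifelog` tibble of stationary events with a `trace`
#'   list-column of `(lat, lon)` tibbles (or `lat`/`lon` columns).
#' @param radius_m Linkage threshold, meters.
#' @return Tibble of clusters: `cluster_id`, `cluster_type`
#'   (`"stationary_place"`), `n_members`, `member_ids` (list),
#'   `rep_lat`, `rep_lon`, `per_instance_duration`, and member row indices.
#' @export
cluster_stationary <- function(events, radius_m = 150) {
  ev <- as_tibble(events)
  loc <- event_locations(ev)
  has_loc <- complete.cases(loc)
  out <- list()
  if (any(has_loc)) {
    pts <- loc[has_loc, , drop = FALSE]
    ids <- which(has_loc)
    if (nrow(pts) == 1L) {
      grp <- 1L
    } else {
      d <- haversine_dist_matrix(pts$lat, pts$lon)
      hc <- stats::hclust(stats::as.dist(d), method = "single")
      grp <- stats::cutree(hc, h = radius_m)
    }
    # stable ids: number clusters by first (chronological) appearance
    grp <- match(grp, unique(grp))
    out$located <- tibble(member = ids, grp = grp, lat = pts$lat,
                          lon = pts$lon) %>%
      group_by(.data$grp) %>%
      summarise(
        member_ids = list(.data$member),
        n_members = dplyr::n(),
        rep_lat = mean(.data$lat),
        rep_lon = mean(.data$lon),
        .groups = "drop"
      ) %>%
      mutate(cluster_id = sprintf("stat_%03d", .data$grp)) %>%
      select(-"grp")
  }
  if (any(!has_loc)) {
    out$unlocated <- tibble(
      member_ids = list(which(!has_loc)),
      n_members = sum(!has_loc),
      rep_lat = NA_real_, rep_lon = NA_real_,
      cluster_id = "unlocated"
    )
  }
  clusters <- list_rbind(out)
  clusters %>%
    mutate(
      cluster_type = "stationary_place",
      per_instance_duration = map_dbl(
        .data$member_ids, ~ mean(ev$duration_min[.x])
      )
    ) %>%
    select(
      "cluster_id", "cluster_type", "n_members", "member_ids",
      "rep_lat", "rep_lon", "per_instance_duration"
    )
}

event_locations <- function(ev) {
  if ("trace" %in% names(ev)) {
    lat <- map_dbl(ev$trace, function(tr) {
      if (is.null(tr) || nrow(tr) == 0) NA_real_ else median(tr$lat)
    })
    lon <- map_dbl(ev$trace, function(tr) {
      if (is.null(tr) || nrow(tr) == 0) NA_real_ else median(tr$lon)
    })
    tibble(lat = lat, lon = lon)
  } else if (all(c("lat", "lon") %in% names(ev))) {
    tibble(lat = ev$lat, lon = ev$lon)
  } else {
    tibble(lat = rep(NA_real_, nrow(ev)), lon = NA_real_)
  }
}

haversine_dist_matrix <- function(lat, lon) {
  n <- length(lat)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d[i, j] <- d[j, i] <- haversine_m(lon[i], lat[i], lon[j], lat[j])
  }
  d
}

#' Resample a GPS trace to a canonical trajectory
#'
#' Arc-length-uniform resampling to `m` points: the canonical form used for
#' shape comparison, analogous to normalizing handwritten strokes before
#' matching them to letter templates. Endpoints are preserved and the
#' resampled path length stays within 1% of the original polyline length.
#'
#' @param trace Tibble with `lat`, `lon` (>= 2 distinct points).
#' @param m Number of output points.
#' @return Tibble of class `canonical_trajectory` with `lat`, `lon` and
#'   attribute `path_length_m`.
#' @export
resample_trajectory <- function(trace, m = 32) {
  tr <- as_tibble(trace)[, c("lat", "lon")]
  tr <- tr[complete.cases(tr), ]
  if (nrow(tr) < 2 || nrow(distinct(tr)) < 2) {
    abort("A trajectory needs at least 2 distinct points.")
  }
  seg <- haversine_m(
    tr$lon[-nrow(tr)], tr$lat[-nrow(tr)], tr$lon[-1], tr$lat[-1]
  )
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  target <- seq(0, total, length.out = m)
  lat <- stats::approx(cum, tr$lat, xout = target, ties = "ordered")$y
  lon <- stats::approx(cum, tr$lon, xout = target, ties = "ordered")$y
  out <- tibble(lat = lat, lon = lon)
  attr(out, "path_length_m") <- sum(haversine_m(
    lon[-m], lat[-m], lon[-1], lat[-1]
  ))
  class(out) <- c("canonical_trajectory", class(out))
  out
}

#' Mean point-wise distance between two canonical trajectories
#'
#' Index-aligned (start to start) mean haversine distance in meters.
#' Symmetric, non-negative, zero only for identical trajectories, and
#' direction-sensitive: a path and its reverse are far apart.
#'
#' @param a,b Canonical trajectories with the same number of points.
#' @return Distance in meters.
#' @export
trajectory_distance <- function(a, b) {
  if (nrow(a) != nrow(b)) {
    abort("Trajectories must have the same number of points.")
  }
  mean(haversine_m(a$lon, a$lat, b$lon, b$lat))
}

#' Cluster walking/running events by trajectory shape and location
#'
#' Leader clustering in chronological (arrival) order: each event's
#' canonical trajectory joins the nearest existing cluster representative
#' if their [trajectory_distance()] is at most `threshold_m`, else it
#' founds a new cluster. Representatives are the point-wise mean of member
#' trajectories. Direction matters: an A-to-B commute and its B-to-A
#' reverse form separate clusters. Walking and running events never mix.
#'
#' @param events `lifelog` tibble of walking/running events with a `trace`
#'   list-column.
#' @param threshold_m Join threshold, meters (defaults to the same 150 m
#'   localization scale used for stationary places).
#' @param m Canonical trajectory resolution.
#' @return Tibble of clusters: `cluster_id`, `cluster_type`
#'   (`"trajectory"`), `label`, `n_members`, `member_ids`,
#'   `representative` (list of canonical trajectories), `rep_lat`,
#'   `rep_lon`, `path_length_m`, `per_instance_duration`.
#' @export
cluster_trajectories <- function(events, threshold_m = 150, m = 32) {
  ev <- as_tibble(events)
  if (nrow(ev) == 0L) {
    return(tibble(
      cluster_id = character(), cluster_type = character(),
      label = character(), n_members = integer(),
      member_ids = list(), representative = list(),
      rep_lat = numeric(), rep_lon = numeric(),
      path_length_m = numeric(), per_instance_duration = numeric()
    ))
  }
  ord <- order(ev$start)
  reps <- list() # per cluster: canonical m x 2 matrix (lat, lon)
  sums <- list() # running sums for the point-wise mean
  members <- list()
  labels <- character()
  for (i in ord) {
    tr <- resample_trajectory(ev$trace[[i]], m = m)
    lab <- ev$label[i]
    cand <- which(labels == lab)
    joined <- FALSE
    if (length(cand)) {
      d <- vapply(cand, function(cid) {
        trajectory_distance(tr, reps[[cid]])
      }, numeric(1))
      best <- cand[which.min(d)] # ties: lowest cluster id wins
      if (min(d) <= threshold_m) {
        members[[best]] <- c(members[[best]], i)
        sums[[best]]$lat <- sums[[best]]$lat + tr$lat
        sums[[best]]$lon <- sums[[best]]$lon + tr$lon
        k <- length(members[[best]])
        mean_tr <- tibble(
          lat = sums[[best]]$lat / k, lon = sums[[best]]$lon / k
        )
        reps[[best]] <- resample_trajectory(mean_tr, m = m)
        joined <- TRUE
      }
    }
    if (!joined) {
      cid <- length(reps) + 1L
      reps[[cid]] <- tr
      sums[[cid]] <- list(lat = tr$lat, lon = tr$lon)
      members[[cid]] <- i
      labels[cid] <- lab
    }
  }
  tibble(
    cluster_id = sprintf("traj_%03d", seq_along(reps)),
    cluster_type = "trajectory",
    label = labels,
    n_members = lengths(members),
    member_ids = members,
    representative = reps,
    rep_lat = map_dbl(reps, ~ mean(.x$lat)),
    rep_lon = map_dbl(reps, ~ mean(.x$lon)),
    path_length_m = map_dbl(reps, ~ attr(.x, "path_length_m")),
    per_instance_duration = map_dbl(members, ~ mean(ev$duration_min[.x]))
  )
}

#' Cluster food events by ingredient similarity
#'
#' Events are first split into meals and snacks (an event in a standard
#' meal window 07-09, 12-14 or 18-21 local time, or with at least 250
#' kcal, is a meal), then leader-clustered within each type by Jaccard
#' similarity of the ingredient token sets from the food table: an event
#' joins the most similar existing cluster when similarity is at least
#' `similarity_threshold`, else founds a new one. Two burgers sharing most
#' ingredients therefore land in one "burger" cluster; meals and snacks
#' never mix.
#'
#' @param events `lifelog` tibble of food events (`label` = `food_id`).
#' @param food_table Tibble from [read_food_table()].
#' @param similarity_threshold Jaccard threshold in `[0, 1]`.
#' @return Tibble of clusters: `cluster_id`, `cluster_type` (`"meal"` or
#'   `"snack"`), `n_members`, `member_ids`, `rep_food_id`, `rep_name`,
#'   `per_instance_kcal`.
#' @export
cluster_foods <- function(events, food_table = read_food_table(),
                          similarity_threshold = 0.5) {
  ev <- as_tibble(events)
  if (nrow(ev) == 0L) {
    return(tibble(
      cluster_id = character(), cluster_type = character(),
      n_members = integer(), member_ids = list(),
      rep_food_id = character(), rep_name = character(),
      per_instance_kcal = numeric()
    ))
  }
  unknown <- setdiff(unique(ev$label), food_table$food_id)
  if (length(unknown)) {
    abort(sprintf(
      "Unknown food_id(s): %s.", paste(unknown, collapse = ", ")
    ))
  }
  ing <- food_table$ingredients[match(ev$label, food_table$food_id)]
  type <- ifelse(is_meal(ev$start, ev$kcal), "meal", "snack")
  ord <- order(ev$start)
  members <- list()
  c_type <- character()
  c_ing <- list()
  for (i in ord) {
    cand <- which(c_type == type[i])
    joined <- FALSE
    if (length(cand)) {
      sim <- vapply(cand, function(cid) {
        jaccard(ing[[i]], c_ing[[cid]])
      }, numeric(1))
      best <- cand[which.max(sim)] # ties: lowest cluster id
      if (max(sim) >= similarity_threshold) {
        members[[best]] <- c(members[[best]], i)
        joined <- TRUE
      }
    }
    if (!joined) {
      cid <- length(members) + 1L
      members[[cid]] <- i
      c_type[cid] <- type[i]
      c_ing[[cid]] <- ing[[i]] # founder's ingredients represent the cluster
    }
  }
  tibble(
    cluster_id = sprintf("food_%03d", seq_along(members)),
    cluster_type = c_type,
    n_members = lengths(members),
    member_ids = members,
    rep_food_id = map_chr(members, function(ix) {
      names(sort(table(ev$label[ix]), decreasing = TRUE))[1]
    }),
    per_instance_kcal = map_dbl(members, ~ mean(ev$kcal[.x]))
  ) %>%
    mutate(
      rep_name = food_table$name[match(.data$rep_food_id,
                                       food_table$food_id)]
    )
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) {
    return(0)
  }
  length(intersect(a, b)) / u
}

#' Is a food event a meal (vs a snack)?
#'
#' @param time POSIXct event time(s).
#' @param kcal Event calories.
#' @param kcal_cutoff Calorie level at or above which any event counts as a
#'   meal regardless of time.
#' @return Logical vector.
#' @export
is_meal <- function(time, kcal, kcal_cutoff = 250) {
  hr <- as.numeric(format(time, "%H")) + as.numeric(format(time, "%M")) / 60
  in_window <- (hr >= 7 & hr < 9) | (hr >= 12 & hr < 14) |
    (hr >= 18 & hr < 21)
  in_window | (!is.na(kcal) & kcal >= kcal_cutoff)
}

#' Cluster a full life log into behavior clusters
#'
#' Runs all cluster types over one life log: stationary places, walking
#' and running trajectories, manual exercise by activity type, and food by
#' ingredients. Every eligible event lands in exactly one cluster. Each
#' cluster's `frequency` is its member count within the trailing
#' `window_days` (default 14) ending at the last event in the log, and
#' `per_instance_kcal`/`per_instance_duration` are means over members.
#'
#' @param lifelog A `lifelog` tibble.
#' @param food_table Food lookup table.
#' @param radius_m,threshold_m,similarity_threshold Stage thresholds.
#' @param window_days Trailing frequency window.
#' @return A `behavior_clusters` tibble; `member_ids` indexes rows of
#'   `lifelog`.
#' @export
cluster_lifelog <- function(lifelog,
                            food_table = read_food_table(),
                            radius_m = 150,
                            threshold_m = 150,
                            similarity_threshold = 0.5,
                            window_days = 14) {
  ll <- as_tibble(lifelog)
  ll$.row <- seq_len(nrow(ll))
  parts <- list()

  stat <- ll %>% filter(.data$kind == "activity",
                        .data$label == "stationary")
  if (nrow(stat)) {
    cs <- cluster_stationary(stat, radius_m = radius_m)
    cs$member_ids <- map(cs$member_ids, ~ stat$.row[.x])
    parts$stationary <- cs
  }

  traj <- ll %>% filter(.data$kind == "activity",
                        .data$label %in% c("walking", "running"))
  if (nrow(traj)) {
    has_trace <- map_lgl(traj$trace %||% vector("list", nrow(traj)),
                         ~ !is.null(.x) && nrow(.x) >= 2)
    tr <- traj[has_trace, ]
    if (nrow(tr)) {
      ct <- cluster_trajectories(tr, threshold_m = threshold_m)
      ct$member_ids <- map(ct$member_ids, ~ tr$.row[.x])
      parts$trajectory <- ct
    }
  }

  man <- ll %>% filter(.data$kind == "manual_exercise")
  if (nrow(man)) {
    parts$manual <- man %>%
      group_by(.data$label) %>%
      summarise(
        member_ids = list(.data$.row),
        n_members = dplyr::n(),
        per_instance_duration = mean(.data$duration_min),
        .groups = "drop"
      ) %>%
      arrange(.data$label) %>%
      mutate(
        cluster_id = sprintf("man_%03d", row_number()),
        cluster_type = "manual_exercise_type"
      )
  }

  food <- ll %>% filter(.data$kind == "food")
  if (nrow(food)) {
    cf <- cluster_foods(food, food_table,
                        similarity_threshold = similarity_threshold)
    cf$member_ids <- map(cf$member_ids, ~ food$.row[.x])
    parts$food <- cf
  }

  clusters <- bind_rows(parts)
  if (nrow(clusters) == 0L) {
    return(structure(clusters, class = c("behavior_clusters",
                                         class(clusters))))
  }
  now <- max(ll$end)
  window_start <- now - window_days * 86400
  kcal_col <- ll$kcal %||% rep(NA_real_, nrow(ll))
  clusters <- clusters %>%
    mutate(
      frequency = map_int(.data$member_ids, function(ix) {
        sum(ll$start[ix] >= window_start)
      }),
      per_instance_kcal = map_dbl(.data$member_ids,
                                  ~ mean(kcal_col[.x])),
      per_instance_duration = map_dbl(.data$member_ids,
                                      ~ mean(ll$duration_min[.x])),
      window_days = window_days
    )
  structure(clusters, class = c("behavior_clusters", class(clusters)))
}
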