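# Readers/writers for the package's plain-text interchange formats:
# sensor CSV (1 Hz), food-log CSV, life-log JSONL, clusters JSON and
# daily suggestion JSON. Timestamps are ISO-8601 UTC; coordinates WGS84.

ts_iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

parse_ts <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' Write / read a 1 Hz sensor stream CSV
#'
#' Columns: `timestamp_iso,ax,ay,az,lat,lon` (accelerometer in g).
#'
#' @param stream Sensor tibble with `timestamp`, `ax`, `ay`, `az`,
#'   `lat`, `lon`.
#' @param path File path.
#' @return `read_sensor_csv` returns the stream tibble.
#' @export
write_sensor_csv <- function(stream, path) {
  out <- tibble(
    timestamp_iso = ts_iso(stream$timestamp),
    ax = stream$ax, ay = stream$ay, az = stream$az,
    lat = stream$lat, lon = stream$lon
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_sensor_csv
#' @export
read_sensor_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    timestamp_iso = readr::col_character(),
    ax = readr::col_double(), ay = readr::col_double(),
    az = readr::col_double(),
    lat = readr::col_double(), lon = readr::col_double()
  ))
  raw %>%
    mutate(timestamp = parse_ts(.data$timestamp_iso)) %>%
    select("timestamp", "ax", "ay", "az", "lat", "lon")
}

#' Write / read a food-log CSV
#'
#' Columns: `timestamp_iso,food_id,quantity`.
#'
#' @param food_log Tibble with `timestamp`, `food_id`, `quantity`.
#' @param path File path.
#' @export
write_food_csv <- function(food_log, path) {
  out <- tibble(
    timestamp_iso = ts_iso(food_log$timestamp),
    food_id = food_log$food_id,
    quantity = food_log$quantity
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_food_csv
#' @export
read_food_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    timestamp_iso = readr::col_character(),
    food_id = readr::col_character(),
    quantity = readr::col_double()
  ))
  raw %>%
    mutate(timestamp = parse_ts(.data$timestamp_iso)) %>%
    select("timestamp", "food_id", "quantity")
}

#' Write / read a life log as JSONL
#'
#' One life event per line with ISO-8601 timestamps; traces and mixed
#' constituents are embedded as arrays.
#'
#' @param lifelog A `lifelog` tibble.
#' @param path File path.
#' @export
write_lifelog_jsonl <- function(lifelog, path) {
  ll <- as_tibble(lifelog)
  lines <- vapply(seq_len(nrow(ll)), function(i) {
    rec <- list(
      start = ts_iso(ll$start[i]),
      end = ts_iso(ll$end[i]),
      kind = ll$kind[i],
      label = ll$label[i],
      duration_min = ll$duration_min[i]
    )
    if ("kcal" %in% names(ll)) rec$kcal <- ll$kcal[i]
    if ("trace" %in% names(ll) && !is.null(ll$trace[[i]])) {
      rec$trace <- as.data.frame(ll$trace[[i]])
    }
    if ("constituents" %in% names(ll) && !is.null(ll$constituents[[i]])) {
      rec$constituents <- as.data.frame(ll$constituents[[i]])
    }
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_lifelog_jsonl
#' @export
read_lifelog_jsonl <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    tibble(
      start = parse_ts(rec$start),
      end = parse_ts(rec$end),
      kind = rec$kind,
      label = rec$label,
      duration_min = rec$duration_min,
      kcal = rec$kcal %||% NA_real_,
      trace = list(if (is.null(rec$trace)) NULL else as_tibble(rec$trace)),
      constituents = list(
        if (is.null(rec$constituents)) NULL else as_tibble(rec$constituents)
      )
    )
  })
  as_lifelog_tbl(list_rbind(rows))
}

#' Write behavior clusters as JSON
#'
#' @param clusters A `behavior_clusters` tibble.
#' @param path File path.
#' @export
write_clusters_json <- function(clusters, path) {
  cl <- as_tibble(clusters)
  recs <- lapply(seq_len(nrow(cl)), function(i) {
    rec <- list(
      cluster_id = cl$cluster_id[i],
      cluster_type = cl$cluster_type[i],
      n_members = cl$n_members[i],
      member_ids = cl$member_ids[[i]],
      frequency = cl$frequency[i],
      per_instance_kcal = cl$per_instance_kcal[i],
      per_instance_duration = cl$per_instance_duration[i]
    )
    if (!is.null(cl$representative[[i]] %||% NULL)) {
      rec$representative <- as.data.frame(cl$representative[[i]])
    }
    for (f in c("rep_lat", "rep_lon", "rep_food_id", "rep_name", "label")) {
      if (f %in% names(cl) && !is.na(cl[[f]][i])) rec[[f]] <- cl[[f]][i]
    }
    rec
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a day's suggestion batches as JSON
#'
#' @param batches Tibble of suggestion rows (activity and food batches
#'   row-bound), as produced by [generate_daily_batch()].
#' @param path File path.
#' @export
write_suggestions_json <- function(batches, path) {
  jsonlite::write_json(
    as.data.frame(batches) %>%
      mutate(date = as.character(.data$date)),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Validate pipeline input files
#'
#' Schema-checks sensor, food-log and food-table files and reports
#' violations with row numbers instead of throwing: non-monotone
#' timestamps, missing values, coordinates outside WGS84 range, unknown
#' food ids, non-positive quantities.
#'
#' @param sensor_path,food_path,food_table_path File paths (any may be
#'   `NULL` to skip).
#' @return Tibble of violations: `file`, `row`, `problem` (empty when
#'   everything checks out).
#' @export
validate_inputs <- function(sensor_path = NULL, food_path = NULL,
                            food_table_path = NULL) {
  issues <- list()
  note <- function(file, row, problem) {
    issues[[length(issues) + 1]] <<- tibble(
      file = file, row = as.integer(row), problem = problem
    )
  }
  if (!is.null(sensor_path)) {
    if (!file.exists(sensor_path)) {
      note(sensor_path, NA, "file not found")
    } else {
      s <- tryCatch(read_sensor_csv(sensor_path), error = function(e) NULL)
      if (is.null(s)) {
        note(sensor_path, NA, "unparseable sensor CSV")
      } else {
        bad_t <- which(is.na(s$timestamp))
        for (r in bad_t) note(sensor_path, r, "unparseable timestamp")
        if (nrow(s) > 1) {
          nonmono <- which(diff(as.numeric(s$timestamp)) <= 0) + 1
          for (r in nonmono) note(sensor_path, r, "non-monotone timestamp")
        }
        bad_lat <- which(!is.na(s$lat) & abs(s$lat) > 90)
        for (r in bad_lat) note(sensor_path, r, "latitude outside [-90, 90]")
        bad_lon <- which(!is.na(s$lon) & abs(s$lon) > 180)
        for (r in bad_lon) {
          note(sensor_path, r, "longitude outside [-180, 180]")
        }
        bad_a <- which(!complete.cases(s[, c("ax", "ay", "az")]))
        for (r in bad_a) note(sensor_path, r, "missing accelerometer value")
      }
    }
  }
  ft <- NULL
  if (!is.null(food_table_path)) {
    if (!file.exists(food_table_path)) {
      note(food_table_path, NA, "file not found")
    } else {
      ft <- tryCatch(read_food_table(food_table_path),
                     error = function(e) NULL)
      if (is.null(ft)) note(food_table_path, NA, "unparseable food table")
    }
  }
  if (!is.null(food_path)) {
    if (!file.exists(food_path)) {
      note(food_path, NA, "file not found")
    } else {
      f <- tryCatch(read_food_csv(food_path), error = function(e) NULL)
      if (is.null(f)) {
        note(food_path, NA, "unparseable food CSV")
      } else {
        for (r in which(is.na(f$timestamp))) {
          note(food_path, r, "unparseable timestamp")
        }
        for (r in which(f$quantity < 0)) {
          note(food_path, r, "negative quantity")
        }
        if (!is.null(ft)) {
          for (r in which(!f$food_id %in% ft$food_id)) {
            note(food_path, r, "unknown food_id")
          }
        }
      }
    }
  }
  if (length(issues) == 0) {
    tibble(file = character(), row = integer(), problem = character())
  } else {
    list_rbind(issues)
  }
}
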