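#' Configure an end-to-end pipeline run
#'
#' Bundles the file paths, lookup tables, thresholds and seed for
#' [run_pipeline()]. Referenced files are checked to exist up front.
#'
#' @param sensor_path 1 Hz sensor CSV (see [write_sensor_csv()]).
#' @param food_path Food-log CSV.
#' @param out_dir Output directory (created if missing).
#' @param profile [user_profile()].
#' @param manual_entries Optional manual exercise tibble
#'   (`start`, `end`, `activity`).
#' @param food_table_path,met_table_path Optional lookup-table overrides.
#' @param engine [engine_config()].
#' @param training_features Labeled feature tibble to train the activity
#'   classifier on; defaults to windows from the class-conditional
#'   generator matched to the 1 Hz stream model.
#' @param window_s Classification window over the 1 Hz stream, seconds.
#' @param radius_m,threshold_m,similarity_threshold Clustering thresholds.
#' @param seed Root seed for classifier training and explore draws.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sensor_path, food_path, out_dir,
                            profile = user_profile("anon"),
                            manual_entries = NULL,
                            food_table_path = NULL,
                            met_table_path = NULL,
                            engine = engine_config(),
                            training_features = NULL,
                            window_s = 10,
                            radius_m = 150, threshold_m = 150,
                            similarity_threshold = 0.5,
                            seed = 1) {
  for (p in c(sensor_path, food_path, food_table_path, met_table_path)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("Input file does not exist: '%s'.", p))
    }
  }
  structure(
    list(
      sensor_path = sensor_path, food_path = food_path, out_dir = out_dir,
      profile = profile, manual_entries = manual_entries,
      food_table_path = food_table_path, met_table_path = met_table_path,
      engine = engine, training_features = training_features,
      window_s = window_s, radius_m = radius_m, threshold_m = threshold_m,
      similarity_threshold = similarity_threshold,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full suggestion pipeline
#'
#' Stages, in order: classify the sensor stream into per-second activity
#' labels (recognize), aggregate to minutes and merge into life events
#' with mixed-event detection, assemble the life log with food and manual
#' entries, cluster behaviors, and emit one ranked activity batch and one
#' food batch per simulated day. Each stage's output is written under
#' `out_dir` (`lifelog.jsonl`, `clusters.json`,
#' `suggestions_<date>.json`) and the run is deterministic given the
#' seed. Any stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with `lifelog`, `clusters`, `suggestions`
#'   (tibble over all days), and `labels` (per-second).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- function(fmt, ...) {
    if (!quiet) message(sprintf(fmt, ...))
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(force(expr), error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    say("[%s] done in %.2fs", name, as.numeric(Sys.time() - t0,
                                               units = "secs"))
    out
  }
  food_table <- read_food_table(config$food_table_path)
  mets <- met_table(config$met_table_path)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  stream <- stage("read", read_sensor_csv(config$sensor_path))
  food_log <- stage("read", read_food_csv(config$food_path))

  model <- stage("train", {
    feats <- config$training_features %||%
      simulate_accel_windows(
        n_per_class = 120, seed = config$seed, rate_hz = 1, window_s = 10
      )
    fit_activity_gmm(feats, k = 2, seed = config$seed)
  })
  labels <- stage("recognize", classify_stream(stream, model,
                                               window_s = config$window_s))
  say("[recognize] %d seconds labeled", nrow(labels))

  lifelog <- stage("lifelog", {
    minutes <- aggregate_minute(labels)
    events <- build_mixed_events(merge_contiguous(minutes))
    events$trace <- event_traces_from_stream(events, stream)
    assemble_lifelog(events, food_log, config$manual_entries,
                     config$profile, food_table, mets)
  })
  write_lifelog_jsonl(lifelog, file.path(config$out_dir, "lifelog.jsonl"))
  say("[lifelog] %d events", nrow(lifelog))

  clusters <- stage("cluster", cluster_lifelog(
    lifelog, food_table,
    radius_m = config$radius_m, threshold_m = config$threshold_m,
    similarity_threshold = config$similarity_threshold
  ))
  write_clusters_json(clusters,
                      file.path(config$out_dir, "clusters.json"))
  say("[cluster] %d clusters", nrow(clusters))

  suggestions <- stage("suggest", {
    days <- unique(as.Date(lifelog$start))
    eng <- config$engine
    eng$rng_seed <- config$seed
    batches <- lapply(days, function(d) {
      bind_rows(
        generate_daily_batch(clusters, "activity", config$profile, eng,
                             date = d, mets = mets),
        generate_daily_batch(clusters, "food", config$profile, eng,
                             date = d, mets = mets)
      )
    })
    for (i in seq_along(days)) {
      write_suggestions_json(
        batches[[i]],
        file.path(config$out_dir,
                  sprintf("suggestions_%s.json", format(days[i])))
      )
    }
    list_rbind(batches)
  })
  say("[suggest] %d suggestions over %d days", nrow(suggestions),
      dplyr::n_distinct(suggestions$date))

  invisible(list(
    lifelog = lifelog, clusters = clusters, suggestions = suggestions,
    labels = labels
  ))
}

# Slice the GPS columns of the stream per event interval.
event_traces_from_stream <- function(events, stream) {
  ts <- as.numeric(stream$timestamp)
  lapply(seq_len(nrow(events)), function(i) {
    ix <- ts >= as.numeric(events$start[i]) &
      ts < as.numeric(events$end[i])
    if (!any(ix)) {
      return(NULL)
    }
    # thin to ~10 s spacing: plenty for 150 m-scale matching
    sub <- which(ix)
    sub <- sub[seq(1, length(sub), by = 10)]
    tibble(lat = stream$lat[sub], lon = stream$lon[sub])
  })
}
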