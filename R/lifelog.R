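#' Aggregate per-second activity labels to per-minute labels
#'
#' First stage of life-log generation: each whole minute receives the
#' majority label of its seconds. A tie goes to the previous minute's label
#' when that label is among the tied ones; otherwise the fixed class order
#' (stationary < walking < running < driving, then manual labels) decides.
#'
#' @param labels Tibble with `timestamp` (POSIXct, 1 Hz) and `label`.
#' @return Tibble with `minute` (POSIXct, floored) and `label`, one row per
#'   minute present in the input.
#' @export
aggregate_minute <- function(labels) {
  if (nrow(labels) == 0L) {
    return(tibble(minute = as.POSIXct(character(), tz = "UTC"),
                  label = character()))
  }
  min_key <- floor(as.numeric(labels$timestamp) / 60) * 60
  counts <- as.data.frame(table(min_key = min_key, label = labels$label),
                          stringsAsFactors = FALSE)
  counts <- counts[counts$Freq > 0, ]
  by_min <- split(counts, counts$min_key)
  keys <- as.numeric(names(by_min))
  ord <- order(keys)
  by_min <- by_min[ord]
  keys <- keys[ord]
  out <- character(length(by_min))
  prev <- NA_character_
  for (i in seq_along(by_min)) {
    g <- by_min[[i]]
    top <- g$label[g$Freq == max(g$Freq)]
    if (length(top) == 1L) {
      out[i] <- top
    } else if (!is.na(prev) && prev %in% top) {
      out[i] <- prev
    } else {
      out[i] <- top[order(activity_rank(top))][1]
    }
    prev <- out[i]
  }
  tibble(
    minute = as.POSIXct(keys, origin = "1970-01-01", tz = "UTC"),
    label = out
  )
}

#' Merge contiguous same-label minutes into life events
#'
#' Second stage: maximal runs of consecutive minutes carrying the same
#' label become a single activity event whose duration is the run length.
#' A gap in the minute sequence breaks a run. Idempotent when re-applied to
#' its own output (converted back to minutes).
#'
#' @param minute_labels Tibble from [aggregate_minute()].
#' @return A `lifelog` tibble of activity events: `start`, `end`, `kind`
#'   (`"activity"`), `label`, `duration_min`.
#' @export
merge_contiguous <- function(minute_labels) {
  if (nrow(minute_labels) == 0L) {
    return(empty_lifelog())
  }
  ml <- arrange(minute_labels, .data$minute)
  t <- as.numeric(ml$minute)
  new_run <- c(TRUE, ml$label[-1] != ml$label[-nrow(ml)] |
                 diff(t) != 60)
  run <- cumsum(new_run)
  ml %>%
    mutate(run = run) %>%
    group_by(run) %>%
    summarise(
      start = min(.data$minute),
      end = max(.data$minute) + 60,
      label = .data$label[1],
      n_min = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(
      kind = "activity",
      duration_min = as.numeric(.data$n_min)
    ) %>%
    select("start", "end", "kind", "label", "duration_min") %>%
    arrange(.data$start) %>%
    as_lifelog_tbl()
}

#' Combine short heterogeneous activity chains into mixed events
#'
#' Maximal chains of two or more consecutive activity events with at least
#' two distinct labels, where every constituent is shorter than
#' `window_minutes` and every inter-event gap is below `window_minutes`,
#' are replaced by a single `mixed` event spanning the first start to the
#' last end (e.g. walk to the bus stop, wait, ride, walk again: one
#' commute). Events of `window_minutes` or longer are never absorbed, and
#' neither are events already of kind `mixed`, which makes the operation
#' idempotent.
#'
#' @param events `lifelog` tibble of merged activity events, sorted.
#' @param window_minutes Chain window, minutes (default 15).
#' @return A `lifelog` tibble; mixed rows carry `label = "mixed"` and a
#'   `constituents` list-column of `(label, duration_min)` tibbles.
#' @export
build_mixed_events <- function(events, window_minutes = 15) {
  if (nrow(events) == 0L) {
    return(events)
  }
  ev <- arrange(events, .data$start)
  if (!"constituents" %in% names(ev)) {
    ev$constituents <- vector("list", nrow(ev))
  }
  eligible <- ev$kind == "activity" & ev$duration_min < window_minutes
  gap_ok <- c(FALSE, as.numeric(ev$start[-1]) -
                as.numeric(ev$end[-nrow(ev)]) < window_minutes * 60)
  # chain id: start a new chain whenever the event is ineligible or the
  # gap to the previous chained event is too long
  chain <- cumsum(!(eligible & gap_ok & c(FALSE, eligible[-nrow(ev)])))
  out <- split(seq_len(nrow(ev)), chain) %>%
    map(function(ix) {
      rows <- ev[ix, ]
      labs <- rows$label
      if (nrow(rows) >= 2 && all(rows$kind == "activity") &&
            n_distinct(labs) >= 2) {
        tibble(
          start = rows$start[1],
          end = rows$end[nrow(rows)],
          kind = "mixed",
          label = "mixed",
          duration_min = sum(rows$duration_min),
          constituents = list(
            tibble(label = labs, duration_min = rows$duration_min)
          )
        )
      } else {
        rows
      }
    }) %>%
    list_rbind()
  as_lifelog_tbl(arrange(out, .data$start))
}

#' Assemble the chronological life log
#'
#' Interleaves automatically sensed activity events, food-log entries and
#' manually logged exercise into one sorted life log. Manual entries win
#' over overlapping automatic events: the automatic event is truncated (or
#' dropped when fully covered). Activity and mixed events get METS
#' calories; food events get table (or direct label) calories.
#'
#' @param activity_events `lifelog` tibble (after [build_mixed_events()]).
#' @param food_log Tibble with `timestamp`, `food_id`, `quantity`, and
#'   optionally `label_kcal`; may be empty or `NULL`.
#' @param manual_entries Tibble with `start`, `end`, `activity` (a MET-table
#'   name); may be empty or `NULL`.
#' @param profile [user_profile()] supplying body weight.
#' @param food_table,mets Lookup tables.
#' @return A `lifelog` tibble sorted by `start` with columns `start`,
#'   `end`, `kind`, `label`, `duration_min`, `kcal` (and `constituents`
#'   where present).
#' @export
assemble_lifelog <- function(activity_events,
                             food_log = NULL,
                             manual_entries = NULL,
                             profile = user_profile("anon"),
                             food_table = read_food_table(),
                             mets = met_table()) {
  ev <- as_tibble(activity_events)
  if (!is.null(manual_entries) && nrow(manual_entries) > 0) {
    man <- manual_entries %>%
      mutate(
        kind = "manual_exercise",
        label = paste0("manual:", .data$activity),
        duration_min = as.numeric(difftime(.data$end, .data$start,
                                           units = "mins"))
      ) %>%
      select("start", "end", "kind", "label", "duration_min")
    for (i in seq_len(nrow(man))) {
      ev <- truncate_overlaps(ev, man$start[i], man$end[i])
    }
    ev <- bind_rows(ev, man)
  }
  ev$kcal <- event_kcal(ev, profile$weight_kg, mets)
  if (!is.null(food_log) && nrow(food_log) > 0) {
    lk <- if ("label_kcal" %in% names(food_log)) {
      food_log$label_kcal
    } else {
      NA_real_
    }
    food <- food_log %>%
      mutate(
        start = .data$timestamp,
        end = .data$timestamp + 60,
        kind = "food",
        label = .data$food_id,
        duration_min = 1,
        kcal = food_kcal(.data$food_id, .data$quantity, food_table,
                         label_kcal = lk)
      ) %>%
      select("start", "end", "kind", "label", "duration_min", "kcal")
    ev <- bind_rows(ev, food)
  }
  as_lifelog_tbl(arrange(ev, .data$start, .data$kind))
}

# Clip activity/mixed events against a manual [start, end) interval.
truncate_overlaps <- function(ev, m_start, m_end) {
  keep <- list()
  for (i in seq_len(nrow(ev))) {
    row <- ev[i, ]
    if (row$end <= m_start || row$start >= m_end) {
      keep[[length(keep) + 1]] <- row
      next
    }
    # overlap: keep non-overlapping flanks, drop the covered middle
    if (row$start < m_start) {
      left <- row
      left$end <- m_start
      left$duration_min <- as.numeric(difftime(m_start, row$start,
                                               units = "mins"))
      keep[[length(keep) + 1]] <- left
    }
    if (row$end > m_end) {
      right <- row
      right$start <- m_end
      right$duration_min <- as.numeric(difftime(row$end, m_end,
                                                units = "mins"))
      keep[[length(keep) + 1]] <- right
    }
  }
  list_rbind(keep)
}

# kcal for activity/mixed/manual rows; mixed uses the duration-weighted
# sum over constituents, which equals the sum of constituent kcal.
event_kcal <- function(ev, weight_kg, mets) {
  vapply(seq_len(nrow(ev)), function(i) {
    row <- ev[i, ]
    if (row$kind == "mixed" && !is.null(row$constituents[[1]])) {
      cons <- row$constituents[[1]]
      sum(activity_kcal(cons$label, cons$duration_min, weight_kg, mets))
    } else {
      activity_kcal(row$label, row$duration_min, weight_kg, mets)
    }
  }, numeric(1))
}

empty_lifelog <- function() {
  as_lifelog_tbl(tibble(
    start = as.POSIXct(character(), tz = "UTC"),
    end = as.POSIXct(character(), tz = "UTC"),
    kind = character(), label = character(), duration_min = numeric()
  ))
}
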