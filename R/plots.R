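#' Plot a life log as a timeline
#'
#' One horizontal segment per event, colored by label, faceted by day.
#'
#' @param lifelog A `lifelog` tibble.
#' @return A ggplot object.
#' @export
plot_lifelog <- function(lifelog) {
  ll <- as_tibble(lifelog) %>%
    mutate(
      day = as.Date(.data$start),
      h0 = as.numeric(.data$start) %% 86400 / 3600,
      h1 = .data$h0 + as.numeric(.data$end - .data$start,
                                 units = "hours")
    )
  ggplot2::ggplot(ll) +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$h0, xend = .data$h1,
        y = .data$kind, yend = .data$kind, color = .data$label
      ),
      linewidth = 4
    ) +
    ggplot2::facet_wrap(~day, ncol = 1) +
    ggplot2::labs(x = "hour of day", y = NULL, color = "label") +
    ggplot2::theme_minimal()
}

#' Plot trajectory clusters on a lat/lon canvas
#'
#' Draws member traces (thin) and cluster representatives (thick).
#'
#' @param clusters Output of [cluster_trajectories()] (or the trajectory
#'   rows of [cluster_lifelog()]).
#' @param lifelog Optional life log to pull member traces from.
#' @return A ggplot object.
#' @export
plot_trajectory_clusters <- function(clusters, lifelog = NULL) {
  cl <- as_tibble(clusters)
  reps <- map2(cl$representative, cl$cluster_id, function(tr, id) {
    mutate(as_tibble(tr), cluster_id = id)
  }) %>% list_rbind()
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(
      data = reps,
      ggplot2::aes(x = .data$lon, y = .data$lat,
                   color = .data$cluster_id),
      linewidth = 1.2
    ) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "longitude", y = "latitude",
                  color = "cluster") +
    ggplot2::theme_minimal()
  if (!is.null(lifelog)) {
    ll <- as_tibble(lifelog)
    members <- map2(cl$member_ids, cl$cluster_id, function(ix, id) {
      traces <- ll$trace[ix]
      imap(traces, function(tr, j) {
        if (is.null(tr)) {
          return(NULL)
        }
        mutate(as_tibble(tr), cluster_id = id, member = j)
      }) %>% list_rbind()
    }) %>% list_rbind()
    if (!is.null(members) && nrow(members)) {
      p <- p + ggplot2::geom_path(
        data = members,
        ggplot2::aes(
          x = .data$lon, y = .data$lat, color = .data$cluster_id,
          group = interaction(.data$cluster_id, .data$member)
        ),
        alpha = 0.25, linewidth = 0.3
      )
    }
  }
  p
}

#' Box plots of weekly distributions with per-user median trend lines
#'
#' The standard view of a behavior-change trial: per-week distributions
#' of the metric, one panel per arm, with each user's weekly medians
#' joined by a line colored by trend direction (positive vs not).
#'
#' @param object A `trial_report` from [analyze_trial()].
#' @param metric Which metric to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot trial_report
autoplot.trial_report <- function(object,
                                  metric = c("walk_length_minutes",
                                             "meal_kcal"),
                                  ...) {
  metric <- match.arg(metric)
  tr <- object$trends %>%
    filter(.data$metric == !!metric, !.data$insufficient_data)
  long <- tr %>%
    tidyr::pivot_longer(
      cols = c("week1_median", "week2_median", "week3_median"),
      names_to = "week", values_to = "median"
    ) %>%
    mutate(week = as.integer(sub("week(\\d)_median", "\\1", .data$week)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$week, y = .data$median)) +
    ggplot2::geom_line(
      ggplot2::aes(group = .data$user_id, color = .data$direction),
      linewidth = 0.9, alpha = 0.8
    ) +
    ggplot2::geom_point(ggplot2::aes(color = .data$direction), size = 1.5) +
    ggplot2::facet_wrap(~arm) +
    ggplot2::scale_color_manual(
      values = c(positive = "#2e7d32", negative = "#c62828")
    ) +
    ggplot2::scale_x_continuous(breaks = 1:3) +
    ggplot2::labs(
      x = "study week",
      y = if (metric == "walk_length_minutes") {
        "median walk length (min)"
      } else {
        "median meal calories (kcal)"
      },
      color = "trend"
    ) +
    ggplot2::theme_minimal()
}
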