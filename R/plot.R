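#' Timeline plot of sensor events
#'
#' The event log a dashboard shows: one horizontal segment per sensor
#' event, device names on the y axis, time on the x axis, coloured by event
#' type — motion presence and door use as signal intervals, appliance use as
#' consumption intervals.
#'
#' @param events events tibble; pass `devices` to label devices by name.
#' @param devices optional device registry.
#' @return A ggplot object.
#' @export
plot_event_timeline <- function(events, devices = NULL) {
  events <- as_tibble(events)
  if (!is.null(devices)) {
    events <- events %>%
      left_join(validate_devices(devices)[, c("device_id", "name")],
                by = "device_id") %>%
      mutate(label = .data$name)
  } else {
    events$label <- events$device_id
  }
  ggplot2::ggplot(events,
                  ggplot2::aes(x = .data$start, xend = .data$end,
                               y = .data$label, yend = .data$label,
                               colour = .data$event_type)) +
    ggplot2::geom_segment(linewidth = 3, lineend = "butt") +
    ggplot2::labs(x = NULL, y = NULL, colour = "event type") +
    ggplot2::theme_minimal()
}

#' Plot a per-group problem summary
#'
#' Grouped bars of the percentage of participants flagged per problem type,
#' by cognitive-status group.
#'
#' @param object an `adl_summary` tibble from [summarize_problems()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
#' @method autoplot adl_summary
autoplot.adl_summary <- function(object, ...) {
  long <- as_tibble(object) %>%
    select("group", dplyr::ends_with("_pct")) %>%
    tidyr::pivot_longer(-"group", names_to = "problem", values_to = "pct") %>%
    mutate(problem = sub("_pct$", "", .data$problem),
           group = factor(.data$group, levels = PARTICIPANT_GROUPS))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$problem, y = .data$pct,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of participants flagged", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
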