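empty_observations <- function() {
  tibble(observation_id = character(0), device_id = character(0),
         device_name = character(0), feature_of_interest = character(0),
         start = empty_instant(), end = empty_instant(),
         max_watts = numeric(0), mean_watts = numeric(0))
}

#' Wrap sensor events as observations
#'
#' Each sensor event becomes one observation: the sensed interval plus the
#' feature of interest the sensor measures, mapped from the device kind
#' (motion sensors observe room presence, door sensors door state, panic
#' buttons panic state, wall plugs power consumption). Consumption
#' observations also carry the observed maximum and mean wattage.
#'
#' @param events events tibble from [extract_events()].
#' @param devices device registry tibble.
#' @param id_prefix prefix for minted observation ids; make it unique per
#'   participant when graphs from several participants are merged.
#' @return Observations tibble ordered by `start` with columns
#'   `observation_id`, `device_id`, `device_name`, `feature_of_interest`,
#'   `start`, `end`, `max_watts`, `mean_watts`.
#' @export
events_to_observations <- function(events, devices, id_prefix = "obs") {
  devices <- validate_devices(devices)
  events <- as_tibble(events)
  if (nrow(events) == 0) return(empty_observations())
  unknown <- setdiff(unique(events$device_id), devices$device_id)
  if (length(unknown) > 0) {
    abort(paste0("events reference device id(s) absent from registry: ",
                 paste(unknown, collapse = ", ")))
  }
  events %>%
    left_join(devices[, c("device_id", "name", "kind")], by = "device_id") %>%
    arrange(.data$start, .data$device_id) %>%
    mutate(
      observation_id = sprintf("%s_%04d", id_prefix, row_number()),
      device_name = .data$name,
      feature_of_interest = unname(FEATURE_BY_KIND[.data$kind])
    ) %>%
    select("observation_id", "device_id", "device_name",
           "feature_of_interest", "start", "end", "max_watts", "mean_watts")
}

empty_activities <- function() {
  tibble(pk = character(0), name = character(0),
         participant_id = character(0),
         start = empty_instant(), end = empty_instant(),
         duration_s = numeric(0), n_steps = integer(0),
         observation_ids = list())
}

#' Compose observations into ADL activities
#'
#' Template matching replaces the manual clustering of the original study
#' protocol: for each protocol template, observations on its member devices
#' are chained into clusters in which consecutive observation start times
#' differ by at most `max_gap_s`; a cluster containing at least one
#' observation on a trigger device (the task-identifying appliance) becomes
#' an activity. The activity spans all its member observations
#' (`start = min start`, `end = max end`), its step count is the number of
#' member observations, and each observation joins at most one activity:
#' templates are matched in roster order and an observation claimed by an
#' earlier template (or an earlier cluster) is not reused.
#'
#' @param observations observations tibble for a single participant
#'   (single-occupancy assumption), time-ordered or not.
#' @param templates protocol templates tibble (see [default_templates()]).
#' @param participant_id id recorded on every produced activity.
#' @return Activities tibble with columns `pk`, `name`, `participant_id`,
#'   `start`, `end`, `duration_s`, `n_steps` and a list column
#'   `observation_ids`.
#' @export
segment_activities <- function(observations, templates, participant_id) {
  templates <- validate_templates(templates)
  observations <- as_tibble(observations)
  if (nrow(observations) == 0) return(empty_activities())
  observations <- observations %>% arrange(.data$start, .data$observation_id)
  claimed <- character(0)
  acts <- list()
  for (ti in seq_len(nrow(templates))) {
    tpl <- templates[ti, ]
    members <- observations %>%
      filter(.data$device_name %in% tpl$member_devices[[1]],
             !.data$observation_id %in% claimed)
    if (nrow(members) == 0) next
    gap <- c(0, diff(as.numeric(members$start)))
    cluster <- cumsum(gap > tpl$max_gap_s)
    for (cl in unique(cluster)) {
      grp <- members[cluster == cl, ]
      if (!any(grp$device_name %in% tpl$trigger_devices[[1]])) next
      claimed <- c(claimed, grp$observation_id)
      acts[[length(acts) + 1]] <- tibble(
        name = tpl$activity_name,
        participant_id = participant_id,
        start = min(grp$start), end = max(grp$end),
        duration_s = secs_between(min(grp$start), max(grp$end)),
        n_steps = nrow(grp),
        observation_ids = list(grp$observation_id))
    }
  }
  if (length(acts) == 0) return(empty_activities())
  bind_rows(acts) %>%
    arrange(.data$start, .data$name) %>%
    mutate(pk = sprintf("act_%s_%02d", participant_id, row_number())) %>%
    select("pk", "name", "participant_id", "start", "end",
           "duration_s", "n_steps", "observation_ids")
}

#' Write activities as JSON lines
#'
#' One object per activity (pk, name, participant, interval, duration,
#' member observation ids); byte-stable for identical input.
#'
#' @param activities activities tibble from [segment_activities()].
#' @param path file path.
#' @export
write_activities <- function(activities, path) {
  lines <- purrr::pmap_chr(as_tibble(activities),
                           function(pk, name, participant_id, start, end,
                                    duration_s, n_steps, observation_ids, ...) {
    jsonlite::toJSON(list(
      pk = pk, name = name, participant_id = participant_id,
      start = format_instant(start), end = format_instant(end),
      duration_s = round(duration_s, 3), n_steps = n_steps,
      observation_ids = observation_ids
    ), auto_unbox = TRUE, digits = NA)
  })
  writeLines(lines, path)
  invisible(path)
}
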