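#' Per-group problem summary
#'
#' Aggregates detected problems into the per-group statistics clinicians
#' read: for each cognitive-status group, the percentage of participants
#' with at least one problem of each type (a participant with several
#' problems of one type counts once), plus the group's average activity
#' duration and step count. The denominator is the number of participants
#' in the group with at least one activity of the target name — not the
#' group size — because participants who never performed the task cannot be
#' flagged. The missing-steps column is always emitted, even when (as in
#' typical runs) it is all zeros.
#'
#' @param problems problems tibble ([run_rules()] / [tidy()]).
#' @param activities activities tibble.
#' @param roster roster tibble (`participant_id`, `group`).
#' @param activity_name the task being summarised.
#' @return A tibble of class `adl_summary` with one row per group (HC, SCD,
#'   MCI order): `group`, `n_participants`, `avg_duration_s`, `avg_steps`,
#'   `too_long_pct`, `divergence_pct`, `extra_steps_pct`,
#'   `missing_steps_pct`.
#' @export
summarize_problems <- function(problems, activities, roster,
                               activity_name = "Hot Meal Preparation") {
  problems <- as_tibble(problems)
  activities <- as_tibble(activities)
  roster <- validate_roster(roster)
  unknown <- setdiff(unique(problems$patient_id), roster$participant_id)
  if (length(unknown) > 0) {
    abort(paste0("problems reference unknown participant(s): ",
                 paste(unknown, collapse = ", ")))
  }
  acts <- activities %>%
    filter(.data$name == activity_name) %>%
    left_join(roster, by = "participant_id")
  pct_of <- function(type) {
    flagged <- unique(problems$patient_id[problems$type == type])
    function(ids) {
      if (length(ids) == 0) return(0)
      100 * length(intersect(flagged, ids)) / length(ids)
    }
  }
  rows <- purrr::map_dfr(PARTICIPANT_GROUPS, function(g) {
    ga <- acts %>% filter(.data$group == g)
    ids <- unique(ga$participant_id)
    tibble(
      group = g,
      n_participants = length(ids),
      avg_duration_s = if (nrow(ga) == 0) NA_real_ else mean(ga$duration_s),
      avg_steps = if (nrow(ga) == 0) NA_real_ else mean(ga$n_steps),
      too_long_pct = pct_of("TooLongDuration")(ids),
      divergence_pct = pct_of("DivergenceFromProtocol")(ids),
      extra_steps_pct = pct_of("ExtraSteps")(ids),
      missing_steps_pct = pct_of("MissingSteps")(ids)
    )
  })
  structure(rows, class = c("adl_summary", class(rows)))
}

#' @export
#' @method glance adl_summary
glance.adl_summary <- function(x, ...) {
  tibble(n_groups = nrow(x),
         n_participants = sum(x$n_participants),
         max_too_long_pct = max(x$too_long_pct),
         max_divergence_pct = max(x$divergence_pct))
}

#' Write a per-group summary as CSV
#'
#' Columns mirror the published group-comparison tables (percentages to two
#' decimals, averages to two decimals).
#'
#' @param summary an `adl_summary` tibble.
#' @param path file path.
#' @export
write_summary <- function(summary, path) {
  out <- as_tibble(summary) %>%
    mutate(across(c("avg_duration_s", "avg_steps", "too_long_pct",
                    "divergence_pct", "extra_steps_pct",
                    "missing_steps_pct"), ~ round(.x, 2)))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Export a dashboard-ready JSON bundle
#'
#' Serialises the three dashboard sections — a filterable event log (one
#' row per sensor event with device and interval), an activity log (one
#' row per activity with its member observation ids) and a
#' problems-over-time series — with fixed key order and number formatting,
#' so identical inputs give byte-identical JSON. No GUI is rendered; the
#' bundle is the data contract for one.
#'
#' @param events events tibble (with `device_name`, see
#'   [events_to_observations()]; plain events tibbles are accepted and
#'   joined against `devices` when given).
#' @param activities activities tibble.
#' @param problems problems tibble.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @param devices optional device registry used to attach device names to
#'   events.
#' @return The JSON string (invisibly when `path` is given).
#' @export
export_dashboard <- function(events, activities, problems, path = NULL,
                             devices = NULL) {
  events <- as_tibble(events)
  if (!is.null(devices) && nrow(events) > 0) {
    events <- events %>%
      left_join(validate_devices(devices)[, c("device_id", "name")],
                by = "device_id") %>%
      mutate(device_name = .data$name)
  }
  ev <- purrr::pmap(events, function(device_id, event_type, start, end, ...) {
    dots <- list(...)
    list(device_id = device_id,
         device_name = dots$device_name %||% device_id,
         event_type = event_type,
         start = format_instant(start), end = format_instant(end))
  })
  ac <- purrr::pmap(as_tibble(activities),
                    function(pk, name, participant_id, start, end, duration_s,
                             n_steps, observation_ids, ...) {
    list(pk = pk, name = name, participant_id = participant_id,
         start = format_instant(start), end = format_instant(end),
         duration_s = round(duration_s, 3), n_steps = n_steps,
         observation_ids = observation_ids)
  })
  pr <- purrr::pmap(as_tibble(problems),
                    function(problem_iri, type, patient_id, date, rate,
                             activity_pk, ...) {
    rec <- list(type = type, patient_id = patient_id,
                date = format_instant(date), activity_pk = activity_pk)
    if (!is.na(rate)) rec$rate <- round(rate, 3)
    rec
  })
  json <- jsonlite::toJSON(list(events = ev, activities = ac, problems = pr),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
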