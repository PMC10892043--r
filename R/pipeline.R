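#' Run the full pipeline on a synthetic cohort
#'
#' `run_pipeline()` executes simulate → ingest → build activities → build
#' knowledge graph → detect problems → report, entirely in memory, and
#' returns every intermediate product. `run_demo()` wraps it, writing the
#' artifact files a study run would produce (readings, registry, roster,
#' templates, ground-truth plans, events, activities, graph, problems,
#' summary, dashboard) into a directory.
#'
#' @param spec a [cohort_spec()]; all randomness flows from `spec$seed`.
#' @param devices device registry.
#' @param templates protocol templates.
#' @param ingest an [ingest_config()].
#' @param rules an [rule_config()].
#' @return `run_pipeline()`: a list with `roster`, `plans`, `readings`,
#'   `events`, `observations`, `activities`, `kg` (enriched), `problems`,
#'   `summary`. `run_demo()`: the same list, invisibly, with `dir` added.
#' @examples
#' \donttest{
#' res <- run_pipeline(cohort_spec(n_hc = 2, n_scd = 2, n_mci = 2, seed = 7))
#' res$summary
#' }
#' @export
run_pipeline <- function(spec = cohort_spec(),
                         devices = default_devices(),
                         templates = default_templates(devices),
                         ingest = ingest_config(),
                         rules = rule_config()) {
  roster <- generate_cohort(spec)
  sim <- generate_streams(roster, spec, devices)
  per_participant <- if (nrow(sim$readings) > 0) {
    dplyr::group_split(sim$readings, .data$participant_id)
  } else {
    list()
  }
  observations <- list(); activities <- list(); events <- list()
  for (rr in per_participant) {
    pid <- rr$participant_id[1]
    evs <- extract_events(rr, devices, ingest)
    obs <- events_to_observations(evs, devices,
                                  id_prefix = paste0("obs_", pid))
    act <- segment_activities(obs, templates, pid)
    events[[length(events) + 1]] <- evs
    observations[[length(observations) + 1]] <- obs
    activities[[length(activities) + 1]] <- act
  }
  events <- if (length(events)) bind_rows(events) else empty_events()
  observations <- if (length(observations)) bind_rows(observations)
                  else empty_observations()
  activities <- if (length(activities)) bind_rows(activities)
                else empty_activities()
  kg <- to_rdf(activities, observations, roster, devices)
  res <- run_rules(kg, rules)
  summary <- summarize_problems(res$problems, activities, roster,
                                rules$activity_name)
  list(roster = roster, plans = sim$plans, readings = sim$readings,
       events = events, observations = observations,
       activities = activities, kg = res$kg, problems = res$problems,
       summary = summary)
}

#' @rdname run_pipeline
#' @param seed integer seed for the demo cohort.
#' @param dir output directory (created if needed).
#' @export
run_demo <- function(seed = 42L, dir = tempfile("adl_demo_"),
                     spec = cohort_spec(seed = seed)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  devices <- default_devices()
  templates <- default_templates(devices)
  res <- run_pipeline(spec, devices, templates)
  write_readings(res$readings, file.path(dir, "readings.csv"))
  write_devices(devices, file.path(dir, "devices.yaml"))
  write_roster(res$roster, file.path(dir, "roster.yaml"))
  write_templates(templates, file.path(dir, "templates.yaml"))
  plans <- res$plans
  plans$start <- format_instant(plans$start)
  writeLines(jsonlite::toJSON(plans, dataframe = "rows", auto_unbox = TRUE,
                              digits = NA, pretty = TRUE),
             file.path(dir, "plans.json"))
  write_events(res$events, file.path(dir, "events.jsonl"))
  write_activities(res$activities, file.path(dir, "activities.jsonl"))
  write_turtle(res$kg, file.path(dir, "graph.ttl"))
  write_problems(res$problems, file.path(dir, "problems.json"))
  write_summary(res$summary, file.path(dir, "summary.csv"))
  export_dashboard(res$events, res$activities, res$problems,
                   path = file.path(dir, "dashboard.json"), devices = devices)
  invisible(c(res, list(dir = dir)))
}
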