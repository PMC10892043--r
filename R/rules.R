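#' Problem-rule configuration
#'
#' Thresholds and protocol order for the four problem-detection rules,
#' instantiated by default for the hot meal preparation task (the other
#' tasks are configurable).
#'
#' @param activity_name the activity the rules apply to.
#' @param duration_threshold_s an activity strictly longer than this (in
#'   seconds) raises a too-long-duration problem; default 2100 s (35 min),
#'   the clinician-set normal-duration bound.
#' @param extra_steps_threshold strictly more distinct observations than
#'   this raises an extra-steps problem; default 20.
#' @param missing_steps_threshold strictly fewer distinct observations than
#'   this raises a missing-steps problem; default 10.
#' @param protocol_order ordered device names the protocol prescribes; the
#'   divergence rule fires when any combination of one observation per
#'   protocol device violates this chronological order.
#' @return A list with class `adl_rule_config`.
#' @export
rule_config <- function(activity_name = "Hot Meal Preparation",
                        duration_threshold_s = 2100,
                        extra_steps_threshold = 20L,
                        missing_steps_threshold = 10L,
                        protocol_order = c("Cabinet (Food)", "Cooker",
                                           "Fridge Door1")) {
  if (duration_threshold_s <= 0 || extra_steps_threshold <= 0 ||
      missing_steps_threshold <= 0) {
    abort("rule thresholds must be positive")
  }
  if (missing_steps_threshold > extra_steps_threshold) {
    abort("missing_steps_threshold must not exceed extra_steps_threshold")
  }
  structure(
    list(activity_name = activity_name,
         duration_threshold_s = duration_threshold_s,
         extra_steps_threshold = as.integer(extra_steps_threshold),
         missing_steps_threshold = as.integer(missing_steps_threshold),
         protocol_order = protocol_order),
    class = "adl_rule_config"
  )
}

empty_problems <- function() {
  tibble(problem_iri = character(0), type = character(0),
         patient_id = character(0), date = empty_instant(),
         rate = numeric(0), activity_pk = character(0))
}

problem_iri <- function(type, pk) {
  adlr(paste0("problem/", slugify(type), "/", pk))
}

# bind the activity-level pattern every rule starts from:
# ?activity a :Activity ; :activity_pk ?pk ; :activity_name ?name ;
#           :activity_start ?start ; :refersToUser ?patient
match_activities <- function(kg, config) {
  acts <- tibble(activity = kg_instances(kg, adl("Activity")))
  if (nrow(acts) == 0) {
    return(tibble(activity = character(0), activity_pk = character(0),
                  patient_id = character(0), date = empty_instant(),
                  duration_s = numeric(0)))
  }
  name <- kg_pred(kg, adl("activity_name")) %>%
    rename(activity = "subject", name = "object")
  pk <- kg_pred(kg, adl("activity_pk")) %>%
    rename(activity = "subject", activity_pk = "object")
  user <- kg_pred(kg, adl("refersToUser")) %>%
    rename(activity = "subject", patient = "object")
  start <- kg_pred(kg, adl("activity_start")) %>%
    rename(activity = "subject", start = "object")
  dur <- kg_pred(kg, adl("activity_duration")) %>%
    rename(activity = "subject", duration = "object")
  acts %>%
    inner_join(name[, c("activity", "name")], by = "activity") %>%
    filter(.data$name == config$activity_name) %>%
    inner_join(pk[, c("activity", "activity_pk")], by = "activity") %>%
    inner_join(user[, c("activity", "patient")], by = "activity") %>%
    inner_join(start[, c("activity", "start")], by = "activity") %>%
    left_join(dur[, c("activity", "duration")], by = "activity") %>%
    mutate(patient_id = sub(paste0(ADLR, "patient/"), "", .data$patient,
                            fixed = TRUE),
           date = parse_instant(.data$start),
           duration_s = as.numeric(.data$duration)) %>%
    select("activity", "activity_pk", "patient_id", "date", "duration_s")
}

# distinct-observation count per matched activity (count(distinct ?event))
count_steps <- function(kg, matched) {
  co <- kg_pred(kg, adl("consistsOf")) %>%
    rename(activity = "subject", obs = "object") %>% distinct()
  matched %>%
    left_join(count(co, .data$activity, name = "steps"), by = "activity") %>%
    mutate(steps = tidyr::replace_na(.data$steps, 0L))
}

#' Detect activities that took too long
#'
#' Graph-pattern rule: matches every activity of the configured name whose
#' duration strictly exceeds `duration_threshold_s` and emits one
#' too-long-duration problem per match, with the activity start as the
#' problem date and the duration in seconds as the problem rate.
#'
#' @param kg an `adl_kg` containing instance data ([to_rdf()]).
#' @param config an [rule_config()].
#' @return A problems tibble (`problem_iri`, `type`, `patient_id`, `date`,
#'   `rate`, `activity_pk`).
#' @export
rule_too_long_duration <- function(kg, config = rule_config()) {
  m <- match_activities(kg, config)
  skip <- is.na(m$duration_s)
  if (any(skip)) {
    warn(paste0("skipping ", sum(skip), " activity(ies) without a duration"))
    m <- m[!skip, ]
  }
  m %>%
    filter(.data$duration_s > config$duration_threshold_s) %>%
    mutate(problem_iri = problem_iri("TooLongDuration", .data$activity_pk),
           type = "TooLongDuration", rate = .data$duration_s) %>%
    select("problem_iri", "type", "patient_id", "date", "rate",
           "activity_pk")
}

#' Detect activities with extra steps
#'
#' Matches activities whose distinct-observation count strictly exceeds
#' `extra_steps_threshold`; the count is the problem rate.
#'
#' @inheritParams rule_too_long_duration
#' @return A problems tibble.
#' @export
rule_extra_steps <- function(kg, config = rule_config()) {
  count_steps(kg, match_activities(kg, config)) %>%
    filter(.data$steps > config$extra_steps_threshold) %>%
    mutate(problem_iri = problem_iri("ExtraSteps", .data$activity_pk),
           type = "ExtraSteps", rate = as.numeric(.data$steps)) %>%
    select("problem_iri", "type", "patient_id", "date", "rate",
           "activity_pk")
}

#' Detect activities with missing steps
#'
#' Matches activities whose distinct-observation count is strictly below
#' `missing_steps_threshold`; the count is the problem rate.
#'
#' @inheritParams rule_too_long_duration
#' @return A problems tibble.
#' @export
rule_missing_steps <- function(kg, config = rule_config()) {
  count_steps(kg, match_activities(kg, config)) %>%
    filter(.data$steps < config$missing_steps_threshold) %>%
    mutate(problem_iri = problem_iri("MissingSteps", .data$activity_pk),
           type = "MissingSteps", rate = as.numeric(.data$steps)) %>%
    select("problem_iri", "type", "patient_id", "date", "rate",
           "activity_pk")
}

#' Detect divergence from the protocol's device order
#'
#' The protocol prescribes a strict chronological order of devices (by
#' default food cabinet, then cooker, then fridge door). For each matched
#' activity containing at least one observation on every protocol device,
#' the rule enumerates every combination of one observation per device
#' (a relational join, as in the declarative query form) and fires when at
#' least one combination violates the strict order of start times. An
#' activity lacking any protocol device is not applicable and never fires.
#'
#' @inheritParams rule_too_long_duration
#' @return A problems tibble (`rate` is `NA`; `activity_pk` identifies the
#'   problematic activity).
#' @export
rule_divergence <- function(kg, config = rule_config()) {
  m <- match_activities(kg, config)
  if (nrow(m) == 0 || length(config$protocol_order) < 2) {
    return(empty_problems())
  }
  co <- kg_pred(kg, adl("consistsOf")) %>%
    rename(activity = "subject", obs = "object") %>% distinct()
  ot <- kg_pred(kg, adl("observation_start_time")) %>%
    rename(obs = "subject", time = "object")
  od <- kg_pred(kg, adl("refersToDevice")) %>%
    rename(obs = "subject", device = "object")
  dn <- kg_pred(kg, adl("device_name")) %>%
    rename(device = "subject", device_name = "object")
  obs <- co %>%
    inner_join(ot[, c("obs", "time")], by = "obs") %>%
    inner_join(od[, c("obs", "device")], by = "obs") %>%
    inner_join(dn[, c("device", "device_name")], by = "device") %>%
    mutate(t = as.numeric(parse_instant(.data$time)))
  # one join per protocol position builds the (e1, ..., ek) combinations
  combos <- m[, "activity", drop = FALSE]
  for (i in seq_along(config$protocol_order)) {
    step <- obs %>%
      filter(.data$device_name == config$protocol_order[i]) %>%
      select("activity", "t")
    names(step)[2] <- paste0("t", i)
    combos <- inner_join(combos, step, by = "activity",
                         relationship = "many-to-many")
  }
  if (nrow(combos) == 0) return(empty_problems())
  tcols <- paste0("t", seq_along(config$protocol_order))
  in_order <- rep(TRUE, nrow(combos))
  for (i in seq_len(length(tcols) - 1)) {
    in_order <- in_order & (combos[[tcols[i]]] < combos[[tcols[i + 1]]])
  }
  bad <- unique(combos$activity[!in_order])
  m %>%
    filter(.data$activity %in% bad) %>%
    mutate(problem_iri = problem_iri("DivergenceFromProtocol",
                                     .data$activity_pk),
           type = "DivergenceFromProtocol", rate = NA_real_) %>%
    select("problem_iri", "type", "patient_id", "date", "rate",
           "activity_pk")
}

problem_triples <- function(problems) {
  if (nrow(problems) == 0) return(kg_new()$triples)
  pat <- adlr(paste0("patient/", problems$patient_id))
  t <- list(
    triple_iri(problems$problem_iri, iri_rdf_type, adl(problems$type)),
    triple_iri(problems$problem_iri, adl("isProblemOf"), pat),
    lit_datetime(problems$problem_iri, adl("problem_date"), problems$date)
  )
  with_rate <- problems[!is.na(problems$rate), ]
  if (nrow(with_rate) > 0) {
    t[[length(t) + 1]] <- lit_decimal(with_rate$problem_iri,
                                      adl("problem_rate"), with_rate$rate)
  }
  div <- problems[problems$type == "DivergenceFromProtocol", ]
  if (nrow(div) > 0) {
    t[[length(t) + 1]] <- triple_iri(div$problem_iri,
                                     adl("problematicActivity"),
                                     adlr(paste0("activity/", div$activity_pk)))
  }
  bind_rows(t)
}

#' Run all four problem rules and enrich the graph
#'
#' Executes the four rules, mints one deterministic problem IRI per
#' (rule, activity) pair, asserts the constructed problem triples into the
#' graph (type, patient, date, and rate or problematic activity — four
#' triples per problem) and returns both. Because problem IRIs are
#' deterministic and a graph is a set of triples, re-running on an already
#' enriched graph adds nothing.
#'
#' @inheritParams rule_too_long_duration
#' @return A list of class `adl_rules_result` with elements `kg` (the
#'   enriched graph) and `problems` (a tibble ordered by `activity_pk`,
#'   then rule type).
#' @export
run_rules <- function(kg, config = rule_config()) {
  problems <- bind_rows(
    rule_too_long_duration(kg, config),
    rule_extra_steps(kg, config),
    rule_missing_steps(kg, config),
    rule_divergence(kg, config)
  )
  if (nrow(problems) == 0) problems <- empty_problems()
  problems <- problems %>% arrange(.data$activity_pk, .data$type)
  structure(list(kg = kg_add(kg, problem_triples(problems)),
                 problems = problems),
            class = "adl_rules_result")
}

#' @export
#' @method print adl_rules_result
print.adl_rules_result <- function(x, ...) {
  cat("<adl_rules_result>", nrow(x$problems), "problem(s);",
      kg_size(x$kg), "triples in enriched graph\n")
  invisible(x)
}

#' @export
#' @method tidy adl_rules_result
tidy.adl_rules_result <- function(x, ...) x$problems

#' @export
#' @method glance adl_rules_result
glance.adl_rules_result <- function(x, ...) {
  p <- x$problems
  tibble(n_problems = nrow(p),
         n_too_long = sum(p$type == "TooLongDuration"),
         n_divergence = sum(p$type == "DivergenceFromProtocol"),
         n_extra_steps = sum(p$type == "ExtraSteps"),
         n_missing_steps = sum(p$type == "MissingSteps"),
         n_patients = dplyr::n_distinct(p$patient_id))
}

#' Brute-force reference implementation of the four rules
#'
#' Applies the four problem rules directly to tabular activity records with
#' explicit loops — no graph, no joins. Used in tests as the independent
#' oracle the graph-pattern engine must agree with.
#'
#' @param activities activities tibble (with `observation_ids` list column).
#' @param observations observations tibble (device names and start times of
#'   every referenced observation).
#' @param config an [rule_config()].
#' @return A problems tibble with the same columns as [run_rules()].
#' @export
brute_force_oracle <- function(activities, observations,
                               config = rule_config()) {
  activities <- as_tibble(activities)
  observations <- as_tibble(observations)
  out <- list()
  emit <- function(type, row, rate) {
    tibble(problem_iri = problem_iri(type, row$pk), type = type,
           patient_id = row$participant_id, date = round_ms(row$start),
           rate = rate, activity_pk = row$pk)
  }
  for (i in seq_len(nrow(activities))) {
    row <- activities[i, ]
    if (row$name != config$activity_name) next
    obs_ids <- unique(row$observation_ids[[1]])
    obs <- observations[match(obs_ids, observations$observation_id), ]
    if (row$duration_s > config$duration_threshold_s) {
      out[[length(out) + 1]] <- emit("TooLongDuration", row, row$duration_s)
    }
    if (length(obs_ids) > config$extra_steps_threshold) {
      out[[length(out) + 1]] <- emit("ExtraSteps", row, length(obs_ids))
    }
    if (length(obs_ids) < config$missing_steps_threshold) {
      out[[length(out) + 1]] <- emit("MissingSteps", row, length(obs_ids))
    }
    # divergence: enumerate every (e1, ..., ek) combination explicitly
    per_dev <- lapply(config$protocol_order, function(d) {
      as.numeric(obs$start[obs$device_name == d])
    })
    if (all(lengths(per_dev) >= 1) && length(per_dev) >= 2) {
      grid <- expand.grid(per_dev, KEEP.OUT.ATTRS = FALSE)
      fired <- FALSE
      for (j in seq_len(nrow(grid))) {
        ts <- as.numeric(grid[j, ])
        if (!all(diff(ts) > 0)) { fired <- TRUE; break }
      }
      if (fired) {
        out[[length(out) + 1]] <- emit("DivergenceFromProtocol", row, NA_real_)
      }
    }
  }
  if (length(out) == 0) return(empty_problems())
  bind_rows(out) %>% arrange(.data$activity_pk, .data$type)
}

#' Write detected problems as JSON
#'
#' @param problems problems tibble.
#' @param path file path.
#' @export
write_problems <- function(problems, path) {
  problems <- as_tibble(problems)
  recs <- purrr::pmap(problems, function(problem_iri, type, patient_id, date,
                                         rate, activity_pk, ...) {
    rec <- list(problem_iri = problem_iri, type = type,
                patient_id = patient_id, date = format_instant(date),
                activity_pk = activity_pk)
    if (!is.na(rate)) rec$rate <- round(rate, 3)
    rec
  })
  writeLines(jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}
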