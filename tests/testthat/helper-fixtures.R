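# shared fixtures: all built in code, no files

ts <- function(x) parse_instant(paste0("2024-03-04T", x, "Z"))

signal_reading <- function(device_id, time, old, new) {
  tibble::tibble(device_id = device_id, timestamp = ts(time),
                 old_value = as.integer(old), new_value = as.integer(new),
                 watts = NA_real_)
}

watt_reading <- function(device_id, time, watts) {
  tibble::tibble(device_id = device_id, timestamp = ts(time),
                 old_value = NA_integer_, new_value = NA_integer_,
                 watts = watts)
}

# a hand-built observation set for one participant: k observations starting
# at the given offsets (seconds after 10:00), on the given device names
make_observations <- function(devices, device_names, offsets_s,
                              id_prefix = "obs", dur_s = 10) {
  stopifnot(length(device_names) == length(offsets_s))
  reg <- devices[match(device_names, devices$name), ]
  start <- ts("10:00:00") + offsets_s
  tibble::tibble(
    observation_id = sprintf("%s_%04d", id_prefix, seq_along(device_names)),
    device_id = reg$device_id,
    device_name = reg$name,
    feature_of_interest = unname(
      c(motion = "MotionFeature", door = "DoorFeature",
        panic = "PanicFeature", wall_plug = "ConsumptionFeature")[reg$kind]),
    start = start, end = start + dur_s,
    max_watts = NA_real_, mean_watts = NA_real_)
}

# one activity record over a set of observations
make_activity <- function(pk, observations, participant_id = "P001",
                          name = "Hot Meal Preparation") {
  tibble::tibble(
    pk = pk, name = name, participant_id = participant_id,
    start = min(observations$start), end = max(observations$end),
    duration_s = as.numeric(max(observations$end)) -
      as.numeric(min(observations$start)),
    n_steps = nrow(observations),
    observation_ids = list(observations$observation_id))
}

# random activity/observation set exercising all four rules; returns the
# tabular records and the graph built from them
random_activity_set <- function(n_activities, devices = default_devices(),
                                roster_id = "P001") {
  proto <- c("Cabinet (Food)", "Cooker", "Fridge Door1")
  others <- c("Kitchen Motion", "Cabinet (Dishes)", "Drawer 1", "Drawer 2",
              "Kitchen Door")
  obs_all <- list(); acts <- list()
  for (i in seq_len(n_activities)) {
    k <- sample(3:26, 1)
    # protocol devices present with high probability, sometimes missing
    names_i <- c(sample(proto, sample(0:3, 1)),
                 sample(others, k, replace = TRUE))
    offsets <- sort(round(runif(length(names_i), 0, 3000), 3))
    # random shuffle so protocol order is sometimes violated
    names_i <- sample(names_i)
    obs <- make_observations(devices, names_i, offsets,
                             id_prefix = sprintf("obs_a%03d", i))
    act <- make_activity(sprintf("act_%s_%02d", roster_id, i), obs,
                         participant_id = roster_id)
    # durations spanning the 2100 s threshold
    act$duration_s <- round(runif(1, 1200, 3200), 3)
    act$end <- act$start + act$duration_s
    obs_all[[i]] <- obs
    acts[[i]] <- act
  }
  observations <- dplyr::bind_rows(obs_all)
  activities <- dplyr::bind_rows(acts)
  roster <- tibble::tibble(participant_id = roster_id, group = "HC")
  kg <- to_rdf(activities, observations, roster, devices)
  list(activities = activities, observations = observations,
       roster = roster, kg = kg)
}

expect_same_problems <- function(a, b) {
  key <- c("type", "patient_id", "activity_pk")
  expect_equal(dplyr::arrange(a[, key], type, activity_pk),
               dplyr::arrange(b[, key], type, activity_pk))
}
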