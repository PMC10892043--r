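#' Synthetic cohort specification
#'
#' Defines the study conditions the simulator emulates: a cohort of healthy
#' controls (HC), participants with subjective cognitive decline (SCD) and
#' participants with mild cognitive impairment (MCI), each performing the
#' hot meal preparation task once in an instrumented kitchen. Group-level
#' mean activity durations and step counts, and per-group divergence
#' probabilities, default to the published group statistics for that task;
#' the dispersions are simulator knobs (the study reports only means).
#'
#' @param n_hc,n_scd,n_mci group sizes (defaults 13, 14, 13).
#' @param duration_mean_s named mean activity durations in seconds.
#' @param duration_sd_s common duration standard deviation (truncated normal,
#'   lower bound `duration_min_s`).
#' @param duration_min_s lower truncation bound for durations.
#' @param steps_mean named mean step counts (observations per activity).
#' @param steps_sd step-count standard deviation (rounded normal, floor 1).
#' @param divergence_prob named per-group probability that the participant
#'   executes the protocol devices out of order.
#' @param participation named per-group fraction of participants who
#'   actually perform the task (the study notes not all participants
#'   completed every task); default 1.
#' @param seed integer seed; every sampling decision flows from it.
#' @return A list with class `adl_cohort_spec`.
#' @examples
#' cohort_spec(seed = 1)
#' @export
cohort_spec <- function(n_hc = 13, n_scd = 14, n_mci = 13,
                        duration_mean_s = c(HC = 1782.36, SCD = 2179.81,
                                            MCI = 2399),
                        duration_sd_s = 400,
                        duration_min_s = 300,
                        steps_mean = c(HC = 15.72, SCD = 15.63, MCI = 18.37),
                        steps_sd = 4,
                        divergence_prob = c(HC = 0.81, SCD = 0.81, MCI = 1),
                        participation = c(HC = 1, SCD = 1, MCI = 1),
                        seed = 1L) {
  stopifnot(n_hc >= 0, n_scd >= 0, n_mci >= 0,
            all(duration_mean_s > 0), all(steps_mean > 0),
            all(divergence_prob >= 0 & divergence_prob <= 1),
            all(participation >= 0 & participation <= 1))
  structure(
    list(sizes = c(HC = n_hc, SCD = n_scd, MCI = n_mci),
         duration_mean_s = duration_mean_s, duration_sd_s = duration_sd_s,
         duration_min_s = duration_min_s,
         steps_mean = steps_mean, steps_sd = steps_sd,
         divergence_prob = divergence_prob, participation = participation,
         seed = as.integer(seed)),
    class = "adl_cohort_spec"
  )
}

# truncated normal by inverse-CDF; vectorized over n
rtnorm <- function(n, mean, sd, lower) {
  p_lo <- pnorm(lower, mean, sd)
  qnorm(p_lo + runif(n) * (1 - p_lo), mean, sd)
}

#' Generate a participant roster
#'
#' Deterministic for a fixed spec seed: participants are labelled
#' `P001...` in group order HC, SCD, MCI, each with a visit day (one
#' participant per day, as in a staged pilot).
#'
#' @param spec a [cohort_spec()].
#' @return Roster tibble (`participant_id`, `group`, `visit_date`).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  sizes <- spec$sizes
  n <- sum(sizes)
  if (n == 0) {
    return(tibble(participant_id = character(0), group = character(0),
                  visit_date = as.Date(character(0))))
  }
  tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    group = rep(names(sizes), sizes),
    visit_date = as.Date("2024-03-04") + seq_len(n) - 1
  )
}

#' Generate raw sensor streams for a cohort
#'
#' For each participating participant, samples one hot meal preparation
#' plan (duration from the group's truncated-normal distribution, step
#' count from the group's rounded-normal distribution, divergence flag from
#' the group's divergence probability) and emits the raw readings a
#' smart-home platform would record for it:
#' * a kitchen motion signal spanning the whole activity;
#' * one door open/close signal pair per door step, with the protocol
#'   devices (food cabinet, cooker window, fridge door) in protocol order —
#'   or with the fridge moved before the cabinet when the plan is
#'   divergent;
#' * a cooker wattage series: idle (< 5 W) readings outside the cooking
#'   window and active readings (800–1500 W) inside it.
#'
#' Steps are spaced by `min(duration / steps, 850)` seconds so a generated
#' activity always chains into a single cluster under the default 900 s
#' template gap. The emitted readings carry a `participant_id` column (the
#' simulator's stand-in for the pilot's visit schedule) so the
#' single-occupancy pipeline can be run per participant.
#'
#' @param roster tibble from [generate_cohort()].
#' @param spec a [cohort_spec()]; its `seed` drives all sampling.
#' @param devices device registry (default [default_devices()]).
#' @return A list with `readings` (raw readings tibble with
#'   `participant_id`) and `plans` (ground-truth tibble: `participant_id`,
#'   `group`, `activity_name`, `start`, `duration_s`, `n_steps`,
#'   `divergent`, `device_order` list column).
#' @export
generate_streams <- function(roster, spec = cohort_spec(),
                             devices = default_devices()) {
  devices <- validate_devices(devices)
  roster <- as_tibble(roster)
  set.seed(spec$seed)
  dev_id <- setNames(devices$device_id, devices$name)
  filler_devices <- c("Cabinet (Dishes)", "Drawer 1", "Drawer 2",
                      "Kitchen Door")
  readings <- list()
  plans <- list()
  for (i in seq_len(nrow(roster))) {
    p <- roster[i, ]
    if (runif(1) > spec$participation[[p$group]]) next
    t0 <- round_ms(as.POSIXct(paste0(p$visit_date, " 10:00:00"), tz = "UTC") +
                     round(runif(1, 0, 1800), 3))
    d <- round(rtnorm(1, spec$duration_mean_s[[p$group]], spec$duration_sd_s,
                      spec$duration_min_s), 3)
    k <- max(1L, as.integer(round(rnorm(1, spec$steps_mean[[p$group]],
                                        spec$steps_sd))))
    divergent <- runif(1) < spec$divergence_prob[[p$group]]
    n_slots <- k - 1L               # non-motion observations
    if (n_slots < 3L) divergent <- FALSE  # protocol devices cannot all fit
    g <- min(d / k, 850)
    slot_t <- as.numeric(t0) + seq_len(n_slots) * g
    # device per slot: protocol devices first (order per divergence flag),
    # fillers after; fillers never reuse protocol devices so a conformant
    # plan cannot accidentally contain a violating combination
    proto <- c("Cabinet (Food)", "Cooker", "Fridge Door1")
    if (divergent) proto <- c("Fridge Door1", "Cabinet (Food)", "Cooker")
    if (n_slots >= 3L) {
      slot_dev <- c(proto,
                    sample(filler_devices, n_slots - 3L, replace = TRUE))
    } else {
      slot_dev <- c("Cooker", "Cabinet (Food)")[seq_len(n_slots)]
    }
    # signal events: motion spans the activity; door steps are short
    sig <- list(tibble(device_id = dev_id[["Kitchen Motion"]],
                       t_on = as.numeric(t0), t_off = as.numeric(t0) + d))
    plug <- list()
    for (s in seq_len(n_slots)) {
      nm <- slot_dev[s]
      if (nm == "Cooker") {
        cook_end <- min(slot_t[s] + round(runif(1, 120, 900), 3),
                        as.numeric(t0) + d - 1)
        plug[[length(plug) + 1]] <- tibble(
          device_id = dev_id[["Cooker"]],
          timestamp = round(c(slot_t[s] - 30, slot_t[s],
                              (slot_t[s] + cook_end) / 2, cook_end), 3),
          watts = c(round(runif(1, 0.1, 2), 3),
                    round(runif(2, 800, 1500), 3),
                    round(runif(1, 0.1, 2), 3)))
      } else {
        dur <- round(runif(1, 3, min(15, 0.5 * g)), 3)
        sig[[length(sig) + 1]] <- tibble(
          device_id = dev_id[[nm]],
          t_on = round(slot_t[s], 3), t_off = round(slot_t[s], 3) + dur)
      }
    }
    sig <- bind_rows(sig)
    sig_rows <- tibble(
      device_id = rep(sig$device_id, each = 2),
      timestamp = as.vector(rbind(sig$t_on, sig$t_off)),
      old_value = rep(c(0L, 1L), nrow(sig)),
      new_value = rep(c(1L, 0L), nrow(sig)),
      watts = NA_real_)
    plug_rows <- if (length(plug) > 0) {
      bind_rows(plug) %>%
        mutate(old_value = NA_integer_, new_value = NA_integer_) %>%
        select("device_id", "timestamp", "old_value", "new_value", "watts")
    } else {
      NULL
    }
    rr <- bind_rows(sig_rows, plug_rows) %>%
      mutate(participant_id = p$participant_id)
    readings[[length(readings) + 1]] <- rr
    plans[[length(plans) + 1]] <- tibble(
      participant_id = p$participant_id, group = p$group,
      activity_name = "Hot Meal Preparation",
      start = t0, duration_s = d, n_steps = k,
      divergent = divergent && n_slots >= 3L,
      device_order = list(c("Kitchen Motion", slot_dev)))
  }
  if (length(readings) == 0) {
    return(list(readings = empty_readings() %>%
                  mutate(participant_id = character(0)),
                plans = tibble(participant_id = character(0),
                               group = character(0),
                               activity_name = character(0),
                               start = empty_instant(),
                               duration_s = numeric(0), n_steps = integer(0),
                               divergent = logical(0), device_order = list())))
  }
  readings <- bind_rows(readings) %>%
    mutate(timestamp = round_ms(.POSIXct(.data$timestamp, tz = "UTC"))) %>%
    arrange(.data$participant_id, .data$device_id, .data$timestamp)
  list(readings = readings, plans = bind_rows(plans))
}

#' Write raw readings as CSV
#'
#' Standard raw-stream CSV (`device_id,timestamp,old_value,new_value,watts`,
#' unused cells empty) plus the simulator's `participant_id` column when
#' present.
#'
#' @param readings readings tibble.
#' @param path file path.
#' @export
write_readings <- function(readings, path) {
  out <- as_tibble(readings)
  out$timestamp <- format_instant(out$timestamp)
  readr::write_csv(out, path, na = "")
  invisible(path)
}
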