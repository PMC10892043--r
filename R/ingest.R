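#' Ingestion configuration
#'
#' Controls how raw readings are segmented into sensor events.
#'
#' @param consumption_threshold_watts wattage at or above which an appliance
#'   is classified as in use (default 5 W). Readings strictly below the
#'   threshold are idle; a reading at exactly the threshold opens an event.
#' @param unterminated_policy what to do with a signal switched on but never
#'   switched off before the stream ends: `"close_at_stream_end"` emits an
#'   event ending at the stream's last timestamp with `terminated = FALSE`
#'   (default — the evidence is kept for activity composition), `"drop"`
#'   discards it.
#' @param max_plausible_signal_duration_s signal events longer than this are
#'   assumed to be false negatives (the closing transition was never sensed,
#'   e.g. a cabinet that did not fully close) and are truncated to this
#'   duration by [normalize_events()]. Default 4 hours.
#' @return A list with class `adl_ingest_config`.
#' @examples
#' ingest_config(consumption_threshold_watts = 5)
#' @export
ingest_config <- function(consumption_threshold_watts = 5,
                          unterminated_policy = c("close_at_stream_end", "drop"),
                          max_plausible_signal_duration_s = 14400) {
  if (consumption_threshold_watts <= 0) {
    abort("consumption_threshold_watts must be > 0")
  }
  structure(
    list(
      consumption_threshold_watts = consumption_threshold_watts,
      unterminated_policy = match.arg(unterminated_policy),
      max_plausible_signal_duration_s = max_plausible_signal_duration_s
    ),
    class = "adl_ingest_config"
  )
}

empty_readings <- function() {
  tibble(device_id = character(0), timestamp = empty_instant(),
         old_value = integer(0), new_value = integer(0),
         watts = numeric(0))
}

#' Read raw sensor readings
#'
#' Reads the two raw time-series dialects from a single file: "Signal"
#' rows (boolean state transitions from motion/door/panic sensors, columns
#' `old_value`/`new_value`) and "Consumption" rows (wattage from wall plugs,
#' column `watts`). Accepts CSV (header
#' `device_id,timestamp,old_value,new_value,watts`, unused cells empty) or
#' line-delimited JSON with the same keys. Extra columns (e.g. a simulator's
#' `participant_id`) are preserved.
#'
#' @param path CSV or JSON-lines file.
#' @param devices device registry tibble; readings for unknown devices are
#'   rejected, as are payloads inconsistent with the device kind.
#' @return A tibble sorted by (`device_id`, `timestamp`) with columns
#'   `device_id`, `timestamp` (POSIXct UTC), `old_value`, `new_value`
#'   (integer or NA), `watts` (numeric or NA), plus any extra input columns.
#' @export
read_readings <- function(path, devices) {
  devices <- validate_devices(devices)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) return(empty_readings())
  if (grepl("^\\s*\\{", first)) {
    rows <- jsonlite::stream_in(file(path), verbose = FALSE)
    raw <- as_tibble(rows)
  } else {
    raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(
                             device_id = readr::col_character(),
                             timestamp = readr::col_character(),
                             .default = readr::col_guess()
                           ))
  }
  validate_readings(raw, devices)
}

#' Validate an in-memory readings table
#'
#' Applies the same contract as [read_readings()] to a tibble: timestamps
#' must parse as ISO 8601 instants, device ids must exist in the registry,
#' signal values must be 0/1, wattage non-negative, and the payload kind
#' must match the device kind (wall plugs emit wattage only, all other kinds
#' emit transitions only). Readings whose old and new value coincide are
#' no-ops and are dropped.
#'
#' @inheritParams read_readings
#' @param readings tibble with columns `device_id`, `timestamp` and
#'   `old_value`/`new_value` or `watts`.
#' @return Sorted, validated readings tibble.
#' @export
validate_readings <- function(readings, devices) {
  readings <- as_tibble(readings)
  if (nrow(readings) == 0) return(empty_readings())
  for (col in c("old_value", "new_value", "watts")) {
    if (!col %in% names(readings)) readings[[col]] <- NA
  }
  if (is.character(readings$timestamp)) {
    ts <- parse_instant(readings$timestamp)
    if (anyNA(ts)) {
      bad <- which(is.na(ts))[1]
      abort(paste0("malformed timestamp on line ", bad, ": ",
                   readings$timestamp[bad]))
    }
    readings$timestamp <- ts
  } else {
    readings$timestamp <- round_ms(readings$timestamp)
  }
  unknown <- setdiff(unique(readings$device_id), devices$device_id)
  if (length(unknown) > 0) {
    abort(paste0("readings reference device id(s) absent from registry: ",
                 paste(unknown, collapse = ", ")))
  }
  readings <- left_join(readings,
                        devices[, c("device_id", "kind")], by = "device_id")
  is_plug <- readings$kind == "wall_plug"
  sig <- readings[!is_plug, ]
  if (nrow(sig) > 0) {
    if (anyNA(sig$old_value) || anyNA(sig$new_value) || any(!is.na(sig$watts))) {
      abort("signal devices must carry old_value/new_value and no watts")
    }
    if (!all(sig$old_value %in% c(0, 1)) || !all(sig$new_value %in% c(0, 1))) {
      abort("signal values must be 0 or 1")
    }
  }
  plug <- readings[is_plug, ]
  if (nrow(plug) > 0) {
    if (anyNA(plug$watts) || any(!is.na(plug$old_value)) ||
        any(!is.na(plug$new_value))) {
      abort("wall_plug devices must carry watts and no old/new values")
    }
    if (any(plug$watts < 0)) abort("negative wattage reading")
  }
  # state-change semantics: identical old/new values carry no information
  noop <- !is_plug & readings$old_value == readings$new_value
  readings <- readings[!noop, ]
  readings$kind <- NULL
  readings %>% arrange(.data$device_id, .data$timestamp)
}

empty_events <- function() {
  tibble(device_id = character(0), event_type = character(0),
         start = empty_instant(), end = empty_instant(),
         terminated = logical(0), max_watts = numeric(0),
         mean_watts = numeric(0))
}

#' Segment one device's signal readings into events
#'
#' A signal event opens at a 0 to 1 transition and closes at the next 1 to 0
#' transition of the same device; the closing timestamp is the event end. A
#' repeated 0 to 1 transition without an intervening closure is ignored with
#' a warning (the pairing rule assumes alternation). An event still open when
#' the stream ends is handled per the configured policy: closed at
#' `stream_end` with `terminated = FALSE`, or dropped.
#'
#' @param readings time-ordered readings of a single motion/door/panic
#'   device (columns `device_id`, `timestamp`, `old_value`, `new_value`).
#' @param config an [ingest_config()].
#' @param stream_end instant used to close unterminated events; defaults to
#'   the last reading's timestamp.
#' @return Events tibble (`device_id`, `event_type = "signal"`, `start`,
#'   `end`, `terminated`, `max_watts`/`mean_watts` = NA), ordered by start.
#' @export
extract_signal_events <- function(readings, config = ingest_config(),
                                  stream_end = NULL) {
  readings <- as_tibble(readings)
  if (nrow(readings) == 0) return(empty_events())
  if (length(unique(readings$device_id)) > 1) {
    abort("extract_signal_events expects readings from a single device")
  }
  if (is.unsorted(as.numeric(readings$timestamp))) {
    abort("readings must be time-ordered")
  }
  stream_end <- stream_end %||% readings$timestamp[nrow(readings)]
  open_at <- NULL
  starts <- numeric(0); ends <- numeric(0); term <- logical(0)
  for (i in seq_len(nrow(readings))) {
    old <- readings$old_value[i]; new <- readings$new_value[i]
    if (old == 0 && new == 1) {
      if (!is.null(open_at)) {
        warn(paste0("device ", readings$device_id[1],
                    ": repeated 0→1 transition at ",
                    format_instant(readings$timestamp[i]), " ignored"))
      } else {
        open_at <- readings$timestamp[i]
      }
    } else if (old == 1 && new == 0) {
      if (!is.null(open_at)) {
        starts <- c(starts, as.numeric(open_at))
        ends <- c(ends, as.numeric(readings$timestamp[i]))
        term <- c(term, TRUE)
        open_at <- NULL
      }
      # a 1->0 with no open event is a stray closure; nothing to pair
    }
  }
  if (!is.null(open_at) && config$unterminated_policy == "close_at_stream_end") {
    starts <- c(starts, as.numeric(open_at))
    ends <- c(ends, max(as.numeric(open_at), as.numeric(stream_end)))
    term <- c(term, FALSE)
  }
  if (length(starts) == 0) return(empty_events())
  tibble(device_id = readings$device_id[1], event_type = "signal",
         start = round_ms(.POSIXct(starts, tz = "UTC")),
         end = round_ms(.POSIXct(ends, tz = "UTC")),
         terminated = term, max_watts = NA_real_, mean_watts = NA_real_) %>%
    arrange(.data$start)
}

#' Segment one wall plug's wattage readings into consumption events
#'
#' An appliance is classified as in use when a reading is at or above the
#' configured threshold (default 5 W) and idle strictly below it. An event
#' opens at the first in-use reading while idle and closes at the first
#' subsequent idle reading, whose timestamp is the event end; `max_watts`
#' and `mean_watts` summarise the in-event (in-use) readings. An event still
#' open at stream end is closed at the last reading's timestamp.
#'
#' @param readings time-ordered wattage readings of a single wall plug
#'   (columns `device_id`, `timestamp`, `watts`).
#' @inheritParams extract_signal_events
#' @return Events tibble (`event_type = "consumption"`), ordered by start.
#' @export
extract_consumption_events <- function(readings, config = ingest_config()) {
  readings <- as_tibble(readings)
  if (nrow(readings) == 0) return(empty_events())
  if (length(unique(readings$device_id)) > 1) {
    abort("extract_consumption_events expects readings from a single device")
  }
  if (is.unsorted(as.numeric(readings$timestamp))) {
    abort("readings must be time-ordered")
  }
  if (any(readings$watts < 0)) abort("negative wattage reading")
  thr <- config$consumption_threshold_watts
  active <- readings$watts >= thr
  out <- list()
  open <- NULL  # list(start, watts)
  for (i in seq_len(nrow(readings))) {
    if (active[i] && is.null(open)) {
      open <- list(start = readings$timestamp[i], watts = readings$watts[i])
    } else if (active[i]) {
      open$watts <- c(open$watts, readings$watts[i])
    } else if (!active[i] && !is.null(open)) {
      out[[length(out) + 1]] <- tibble(
        device_id = readings$device_id[1], event_type = "consumption",
        start = open$start, end = readings$timestamp[i], terminated = TRUE,
        max_watts = max(open$watts), mean_watts = mean(open$watts))
      open <- NULL
    }
  }
  if (!is.null(open)) {
    out[[length(out) + 1]] <- tibble(
      device_id = readings$device_id[1], event_type = "consumption",
      start = open$start, end = readings$timestamp[nrow(readings)],
      terminated = FALSE,
      max_watts = max(open$watts), mean_watts = mean(open$watts))
  }
  if (length(out) == 0) return(empty_events())
  bind_rows(out) %>% arrange(.data$start)
}

#' Segment a full multi-device readings table into sensor events
#'
#' Dispatches each device's readings to [extract_signal_events()] or
#' [extract_consumption_events()] according to its registry kind, then
#' applies [normalize_events()]. The stream end used to close unterminated
#' signal events is the latest timestamp in the whole table.
#'
#' @param readings validated readings tibble (see [read_readings()]).
#' @param devices device registry tibble.
#' @param config an [ingest_config()].
#' @return Combined events tibble ordered by (`device_id`, `start`).
#' @export
extract_events <- function(readings, devices, config = ingest_config()) {
  devices <- validate_devices(devices)
  readings <- as_tibble(readings)
  if (nrow(readings) == 0) return(empty_events())
  stream_end <- max(readings$timestamp)
  evs <- readings %>%
    left_join(devices[, c("device_id", "kind")], by = "device_id") %>%
    dplyr::group_split(.data$device_id) %>%
    purrr::map(function(d) {
      kind <- d$kind[1]
      d$kind <- NULL
      if (kind == "wall_plug") {
        extract_consumption_events(d, config)
      } else {
        extract_signal_events(d, config, stream_end = stream_end)
      }
    }) %>%
    bind_rows()
  normalize_events(evs, config) %>% arrange(.data$device_id, .data$start)
}

#' Normalize implausibly long signal events
#'
#' A contact sensor can fail to report a closure (a cabinet door that did not
#' fully close), producing a signal event far longer than any plausible real
#' interaction. Such false negatives are normalized by truncating any signal
#' event longer than `max_plausible_signal_duration_s` to exactly that
#' duration and marking it `terminated = FALSE`. Consumption events and
#' shorter signal events pass through unchanged.
#'
#' @param events events tibble.
#' @param config an [ingest_config()].
#' @return Events tibble of the same shape.
#' @export
normalize_events <- function(events, config = ingest_config()) {
  events <- as_tibble(events)
  if (nrow(events) == 0) return(empty_events())
  cap <- config$max_plausible_signal_duration_s
  too_long <- events$event_type == "signal" &
    secs_between(events$start, events$end) > cap
  events$end[too_long] <- round_ms(events$start[too_long] + cap)
  events$terminated[too_long] <- FALSE
  events
}

#' Write or read events as JSON lines
#'
#' One JSON object per event with explicit ISO 8601 timestamps; key order
#' and number formatting are fixed, so identical inputs give byte-identical
#' files.
#'
#' @param events events tibble.
#' @param path file path.
#' @export
write_events <- function(events, path) {
  events <- as_tibble(events)
  lines <- purrr::pmap_chr(events, function(device_id, event_type, start, end,
                                            terminated, max_watts, mean_watts,
                                            ...) {
    rec <- list(device_id = device_id, event_type = event_type,
                start = format_instant(start), end = format_instant(end),
                terminated = terminated)
    if (!is.na(max_watts)) {
      rec$max_watts <- round(max_watts, 3)
      rec$mean_watts <- round(mean_watts, 3)
    }
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) return(empty_events())
  purrr::map_dfr(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    tibble(device_id = rec$device_id, event_type = rec$event_type,
           start = parse_instant(rec$start), end = parse_instant(rec$end),
           terminated = rec$terminated,
           max_watts = rec$max_watts %||% NA_real_,
           mean_watts = rec$mean_watts %||% NA_real_)
  })
}
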