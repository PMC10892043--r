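DEVICE_KINDS <- c("motion", "door", "panic", "wall_plug")

# device kind -> feature-of-interest class used in the ontology
FEATURE_BY_KIND <- c(
  motion    = "MotionFeature",
  door      = "DoorFeature",
  panic     = "PanicFeature",
  wall_plug = "ConsumptionFeature"
)

PARTICIPANT_GROUPS <- c("HC", "SCD", "MCI")

ADL_TASKS <- c("Hot Meal Preparation", "Hot Beverage Preparation",
               "Cold Meal Preparation")

#' Default smart-home device registry
#'
#' A registry of the device complement of a monitored kitchen: motion, door
#' (door/drawer/cabinet contact) and panic sensors emitting boolean
#' state-change signals, and wall plugs emitting wattage series for the
#' appliances relevant to meal and beverage preparation. Device names are
#' significant: the divergence-from-protocol rule matches observations by the
#' names `"Cabinet (Food)"`, `"Cooker"` and `"Fridge Door1"`.
#'
#' @return A tibble with columns `device_id`, `name`, `kind`
#'   (`motion`/`door`/`panic`/`wall_plug`) and `room`.
#' @examples
#' default_devices()
#' @export
default_devices <- function() {
  dev <- tibble::tribble(
    ~name,              ~kind,       ~room,
    "Kitchen Motion",   "motion",    "kitchen",
    "Living Room Motion", "motion",  "living_room",
    "Cabinet (Food)",   "door",      "kitchen",
    "Cabinet (Dishes)", "door",      "kitchen",
    "Fridge Door1",     "door",      "kitchen",
    "Drawer 1",         "door",      "kitchen",
    "Drawer 2",         "door",      "kitchen",
    "Kitchen Door",     "door",      "kitchen",
    "Panic Button",     "panic",     "kitchen",
    "Cooker",           "wall_plug", "kitchen",
    "Kettle",           "wall_plug", "kitchen",
    "Toaster",          "wall_plug", "kitchen"
  )
  dev$device_id <- paste0("dev_", slugify(dev$name))
  validate_devices(dev[, c("device_id", "name", "kind", "room")])
}

slugify <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_|_$", "", x)
}

validate_devices <- function(devices) {
  devices <- as_tibble(devices)
  required <- c("device_id", "name", "kind", "room")
  missing <- setdiff(required, names(devices))
  if (length(missing) > 0) {
    abort(paste0("device registry lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(devices$device_id)) {
    abort("device_id values must be unique in a registry")
  }
  bad <- setdiff(unique(devices$kind), DEVICE_KINDS)
  if (length(bad) > 0) {
    abort(paste0("unknown device kind(s): ", paste(bad, collapse = ", ")))
  }
  devices[, required]
}

#' Read or write a device registry as YAML
#'
#' The YAML layout is a list of records with keys `name`, `kind`, `room` and
#' optionally `device_id` (minted from the name when absent).
#'
#' @param path file path.
#' @param devices a device registry tibble (see [default_devices()]).
#' @return `read_devices()` returns the validated registry tibble;
#'   `write_devices()` returns `path` invisibly.
#' @export
read_devices <- function(path) {
  raw <- yaml::read_yaml(path)
  dev <- purrr::map_dfr(raw, function(d) {
    tibble(
      device_id = d$device_id %||% paste0("dev_", slugify(d$name)),
      name = d$name, kind = d$kind, room = d$room %||% NA_character_
    )
  })
  validate_devices(dev)
}

#' @rdname read_devices
#' @export
write_devices <- function(devices, path) {
  devices <- validate_devices(devices)
  recs <- purrr::pmap(devices, function(device_id, name, kind, room) {
    list(device_id = device_id, name = name, kind = kind, room = room)
  })
  yaml::write_yaml(recs, path)
  invisible(path)
}

#' Protocol templates for the three scripted ADL tasks
#'
#' A protocol template describes one scripted task: the room it happens in,
#' the devices whose observations may join the activity cluster
#' (`member_devices`), the appliance whose use identifies the task
#' (`trigger_devices`), the maximum gap in seconds between consecutive
#' observation starts for them to chain into one cluster (`max_gap_s`), and
#' the ordered device sequence the protocol prescribes (`ordered_protocol`,
#' used by the divergence rule). The default templates encode the three
#' kitchen tasks — hot meal (trigger: cooker), hot beverage (kettle) and cold
#' meal (toaster) preparation.
#'
#' @param devices device registry used to pick member devices by room.
#' @param max_gap_s maximum chaining gap in seconds (default 900 = 15 min,
#'   well below the 2100 s normal-duration bound so consecutive tasks do not
#'   merge).
#' @return A tibble with columns `activity_name`, `room`, `trigger_devices`,
#'   `member_devices`, `ordered_protocol` (list columns of device names) and
#'   `max_gap_s`.
#' @export
default_templates <- function(devices = default_devices(), max_gap_s = 900) {
  kitchen <- devices$name[devices$room == "kitchen" & devices$kind != "panic"]
  triggers <- list("Cooker", "Kettle", "Toaster")
  members <- purrr::map(triggers, function(tr) {
    setdiff(kitchen, setdiff(c("Cooker", "Kettle", "Toaster"), tr))
  })
  tibble(
    activity_name = ADL_TASKS,
    room = "kitchen",
    trigger_devices = triggers,
    member_devices = members,
    ordered_protocol = list(
      c("Cabinet (Food)", "Cooker", "Fridge Door1"),
      character(0),
      character(0)
    ),
    max_gap_s = max_gap_s
  )
}

#' @rdname default_templates
#' @param path file path for YAML serialization.
#' @export
read_templates <- function(path) {
  raw <- yaml::read_yaml(path)
  tpl <- purrr::map_dfr(raw, function(t) {
    tibble(
      activity_name = t$activity_name,
      room = t$room %||% NA_character_,
      trigger_devices = list(as.character(unlist(t$trigger_devices))),
      member_devices = list(as.character(unlist(t$member_devices))),
      ordered_protocol = list(as.character(unlist(t$ordered_protocol))),
      max_gap_s = as.numeric(t$max_gap_s)
    )
  })
  validate_templates(tpl)
}

#' @rdname default_templates
#' @param templates a template tibble.
#' @export
write_templates <- function(templates, path) {
  templates <- validate_templates(templates)
  recs <- purrr::pmap(templates, function(activity_name, room, trigger_devices,
                                          member_devices, ordered_protocol,
                                          max_gap_s) {
    list(activity_name = activity_name, room = room,
         trigger_devices = as.list(trigger_devices),
         member_devices = as.list(member_devices),
         ordered_protocol = as.list(ordered_protocol),
         max_gap_s = max_gap_s)
  })
  yaml::write_yaml(recs, path)
  invisible(path)
}

validate_templates <- function(templates) {
  templates <- as_tibble(templates)
  if (any(templates$max_gap_s <= 0)) abort("max_gap_s must be > 0")
  ok <- purrr::map2_lgl(templates$ordered_protocol, templates$member_devices,
                        ~ all(.x %in% .y))
  if (!all(ok)) {
    abort("ordered_protocol devices must be a subset of member_devices")
  }
  templates
}

#' Read or write a participant roster
#'
#' A roster assigns each participant to one cognitive-status group: healthy
#' control (HC), subjective cognitive decline (SCD) or mild cognitive
#' impairment (MCI).
#'
#' @param path file path (YAML list of `{participant_id, group}` records).
#' @param roster roster tibble with columns `participant_id`, `group`.
#' @return `read_roster()` returns the validated roster tibble.
#' @export
read_roster <- function(path) {
  raw <- yaml::read_yaml(path)
  roster <- purrr::map_dfr(raw, function(p) {
    tibble(participant_id = p$participant_id, group = p$group)
  })
  validate_roster(roster)
}

#' @rdname read_roster
#' @export
write_roster <- function(roster, path) {
  roster <- validate_roster(roster)
  recs <- purrr::pmap(roster[, c("participant_id", "group")],
                      function(participant_id, group) {
    list(participant_id = participant_id, group = group)
  })
  yaml::write_yaml(recs, path)
  invisible(path)
}

validate_roster <- function(roster) {
  roster <- as_tibble(roster)
  bad <- setdiff(unique(roster$group), PARTICIPANT_GROUPS)
  if (length(bad) > 0) {
    abort(paste0("unknown group(s): ", paste(bad, collapse = ", "),
                 " (expected HC, SCD, MCI)"))
  }
  if (anyDuplicated(roster$participant_id)) {
    abort("participant_id values must be unique")
  }
  roster
}
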