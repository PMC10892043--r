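#' Parse and format ISO 8601 UTC instants
#'
#' All timestamps in adlgraph are UTC `POSIXct` at millisecond precision.
#' `parse_instant()` accepts `"2024-03-04T10:00:00Z"`,
#' `"2024-03-04T10:00:00.250Z"` or a space instead of the `T`;
#' `format_instant()` always emits the `T`/`Z`, millisecond form, so that
#' serialized output is byte-stable.
#'
#' @param x character vector of ISO 8601 instants (`parse_instant`) or a
#'   `POSIXct` vector (`format_instant`).
#' @return `parse_instant()`: `POSIXct` (UTC); `NA` entries where the input
#'   is unparseable. `format_instant()`: character.
#' @examples
#' parse_instant("2024-03-04T10:00:00.500Z")
#' format_instant(parse_instant("2024-03-04T10:00:00Z"))
#' @export
parse_instant <- function(x) {
  y <- sub("Z$", "", sub("T", " ", x, fixed = TRUE))
  out <- as.POSIXct(y, tz = "UTC", format = "%Y-%m-%d %H:%M:%OS")
  round_ms(out)
}

#' @rdname parse_instant
#' @export
format_instant <- function(x) {
  stopifnot(inherits(x, "POSIXct"))
  strftime(round_ms(x), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
}

# round POSIXct to whole milliseconds; avoids float drift in round trips
round_ms <- function(x) {
  structure(round(as.numeric(x) * 1000) / 1000,
            class = c("POSIXct", "POSIXt"), tzone = "UTC")
}

# elapsed seconds between two instants, as a plain numeric (ms precision)
secs_between <- function(start, end) {
  round(as.numeric(end) - as.numeric(start), 3)
}

# empty POSIXct of the right tz, for zero-row tibbles
empty_instant <- function() {
  structure(numeric(0), class = c("POSIXct", "POSIXt"), tzone = "UTC")
}
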