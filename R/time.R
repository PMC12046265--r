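#' Parse an ISO-8601 UTC timestamp
#'
#' All timestamps in the package are UTC. Accepted forms are
#' `"YYYY-MM-DDTHH:MM:SSZ"` (canonical), the same with a space separator, or
#' with a `+00:00` suffix. Anything else -- including non-UTC offsets -- is an
#' error: window arithmetic is done in seconds on UTC clocks so daylight-saving
#' ambiguity can never enter a triage decision.
#'
#' @param x character vector of timestamps, or a `POSIXct` (returned with its
#'   timezone forced to UTC).
#' @return `POSIXct` in UTC.
#' @export
#' @examples
#' parse_utc("2020-03-31T10:00:00Z")
parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (!is.character(x)) {
    stop("timestamp must be a character ISO-8601 UTC string or POSIXct", call. = FALSE)
  }
  x2 <- sub("\\+00:00$", "Z", x)
  x2 <- sub(" ", "T", x2, fixed = TRUE)
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}Z$", x2)
  if (any(!ok)) {
    stop("not an ISO-8601 UTC timestamp: ", paste(x[!ok], collapse = ", "), call. = FALSE)
  }
  out <- as.POSIXct(x2, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")
  if (anyNA(out)) {
    stop("unparseable timestamp: ", paste(x[is.na(out)], collapse = ", "), call. = FALSE)
  }
  out
}

#' Format a timestamp as canonical ISO-8601 UTC
#'
#' @param t `POSIXct`.
#' @return character, `"YYYY-MM-DDTHH:MM:SSZ"`.
#' @export
format_utc <- function(t) {
  format(parse_utc(t), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' Hours elapsed between two instants
#'
#' Computed in seconds then divided by 3600, exact to the second.
#'
#' @param from,to timestamps (ISO-8601 strings or `POSIXct`).
#' @return numeric hours (`to - from`).
#' @export
hours_between <- function(from, to) {
  as.numeric(difftime(parse_utc(to), parse_utc(from), units = "secs")) / 3600
}
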