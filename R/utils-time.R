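# Time handling: all timestamps are timezone-naive local clock times,
# represented as POSIXct in UTC so arithmetic is pure clock arithmetic
# (no DST). Clock times are numeric hours in [0, 24).

#' Parse timestamps from character vectors
#'
#' Accepts ISO-8601 `"YYYY-MM-DDTHH:MM:SS"` (or with a space separator) and
#' returns POSIXct in UTC. Used by all CSV readers; timestamps in this
#' package are timezone-naive local clock times.
#'
#' @param x character vector of timestamps.
#' @return POSIXct vector (UTC).
#' @export
parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- gsub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  out
}

#' Format timestamps as ISO-8601
#' @param x POSIXct vector.
#' @return character vector `"YYYY-MM-DDTHH:MM:SS"`.
#' @export
format_timestamp <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

#' Clock time of a timestamp in hours
#'
#' @param x POSIXct vector.
#' @return numeric hours in `[0, 24)`.
#' @export
clock_hours <- function(x) {
  stopifnot(inherits(x, "POSIXct"))
  lt <- as.POSIXlt(x, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

#' Calendar date of a timestamp
#' @param x POSIXct vector.
#' @return Date vector.
#' @export
calendar_date <- function(x) {
  as.Date(x, tz = "UTC")
}

# hours between two POSIXct
hours_between <- function(from, to) {
  as.numeric(difftime(to, from, units = "hours"))
}

# POSIXct at `date` midnight plus `hours` (hours may exceed 24 meaning the
# following day, e.g. 25.18 = 0111 h next day)
at_clock <- function(date, hours) {
  as.POSIXct(as.POSIXlt(as.Date(date)), tz = "UTC") + hours * 3600
}

#' Parse "HH:MM" clock strings to numeric hours
#' @param x character like `"23:00"`.
#' @return numeric hours.
#' @export
parse_clock <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    p[1] + ifelse(length(p) > 1, p[2] / 60, 0) +
      ifelse(length(p) > 2, p[3] / 3600, 0)
  }, numeric(1))
}

# is clock hour h inside half-open clock interval [a, b), possibly wrapping
# midnight (a > b, e.g. 23 -> 6)
clock_in_interval <- function(h, a, b) {
  if (a <= b) h >= a & h < b else h >= a | h < b
}

# total overlap in hours between interval [s, e] and a set of intervals
# given as two POSIXct vectors
interval_overlap_hours <- function(s, e, starts, ends) {
  if (length(starts) == 0) return(0)
  lo <- pmax(as.numeric(starts), as.numeric(s))
  hi <- pmin(as.numeric(ends), as.numeric(e))
  sum(pmax(hi - lo, 0)) / 3600
}
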