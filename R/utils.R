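# Internal helpers: time arithmetic on epoch-millisecond stamps and small
# validation utilities shared across modules.

MS_PER_DAY <- 86400000
MS_PER_MIN <- 60000

#' @useDynLib mossense, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# quiet R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".SD", "day", "stdev_norm", "kind", "direction", "contact",
  "slot", "t_unlock", "t_lock", "in_moss_app", "interventions_executed"
))

#' Convert an epoch-millisecond stamp to a local calendar day index
#'
#' Days are counted from the Unix epoch after shifting by the subject's
#' UTC offset, so "per day" statistics can follow the subject's clock.
#'
#' @param t numeric vector of epoch milliseconds (UTC).
#' @param tz_offset_min minutes east of UTC (default 0).
#' @return integer day index (days since 1970-01-01, local).
#' @keywords internal
ms_day <- function(t, tz_offset_min = 0) {
  as.integer(floor((t + tz_offset_min * MS_PER_MIN) / MS_PER_DAY))
}

#' @keywords internal
ms_hour <- function(t, tz_offset_min = 0) {
  loc <- (t + tz_offset_min * MS_PER_MIN) %% MS_PER_DAY
  loc / 3600000
}

#' @keywords internal
day_start_ms <- function(day, tz_offset_min = 0) {
  day * MS_PER_DAY - tz_offset_min * MS_PER_MIN
}

#' Assign a day slot to an hour of day
#'
#' Morning is [5, 12), afternoon [12, 18); everything else (evening and
#' night) is "evening".  Boundaries are configurable because the field
#' has no fixed convention.
#'
#' @param hour numeric hour in [0, 24).
#' @param bounds numeric c(morning_start, afternoon_start, evening_start).
#' @return character vector in {"morning", "afternoon", "evening"}.
#' @export
#' @examples
#' day_slot(c(6, 13, 20, 2))
day_slot <- function(hour, bounds = c(5, 12, 18)) {
  stopifnot(length(bounds) == 3, all(diff(bounds) > 0))
  out <- rep("evening", length(hour))
  out[hour >= bounds[1] & hour < bounds[2]] <- "morning"
  out[hour >= bounds[2] & hour < bounds[3]] <- "afternoon"
  out
}

# stop() with a consistent prefix naming the offending stream
stream_error <- function(stream, msg, row = NULL) {
  loc <- if (is.null(row)) "" else sprintf(" (row %d)", row)
  stop(sprintf("stream '%s'%s: %s", stream, loc, msg), call. = FALSE)
}

check_sorted <- function(t, stream) {
  if (length(t) > 1 && any(diff(t) < 0)) {
    stream_error(stream, "timestamps are not sorted",
                 row = which(diff(t) < 0)[1] + 1L)
  }
  invisible(TRUE)
}

# split a ';'-joined BSSID field into a character vector
split_bssids <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

join_bssids <- function(v) paste(v, collapse = ";")

# population variance (divide by n)
pop_var <- function(x) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  mean((x - mean(x))^2)
}

# polynomial rolling hash of a character vector, for config stamping
config_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
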