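# Canonical in-memory representation of one subject's sensor record and
# its on-disk serialisation.  Every downstream module (features,
# aggregation, detection, evaluation) consumes this one container.
#
# Timestamps are UTC epoch milliseconds throughout; the subject's local
# clock enters only through `tz_offset_min` when day boundaries matter.

STREAM_KINDS <- c("accel", "gps", "wifi", "comm", "calendar",
                  "phoneuse", "sessions", "phq9")

stream_templates <- function() {
  list(
    accel    = data.frame(start = numeric(0), stdev_norm = numeric(0)),
    gps      = data.frame(t = numeric(0), lat = numeric(0), lon = numeric(0)),
    wifi     = data.frame(t = numeric(0), bssids = character(0)),
    comm     = data.frame(t = numeric(0), kind = character(0),
                          direction = character(0), contact = character(0),
                          duration = numeric(0)),
    calendar = data.frame(t_start = numeric(0), slot = character(0)),
    phoneuse = data.frame(t_unlock = numeric(0), t_lock = numeric(0),
                          in_moss_app = numeric(0)),
    sessions = data.frame(t = numeric(0), interventions_executed = integer(0)),
    phq9     = data.frame(t = numeric(0), score = integer(0))
  )
}

time_col <- c(accel = "start", gps = "t", wifi = "t", comm = "t",
              calendar = "t_start", phoneuse = "t_unlock", sessions = "t",
              phq9 = "t")

#' Construct a subject stream
#'
#' A `subject_stream` bundles all timestamped event streams recorded for
#' one subject: 2-minute accelerometer activity windows, GPS fixes and
#' WiFi scans at a nominal 15-minute cadence, call/SMS logs, calendar
#' events, phone lock/unlock intervals, app sessions, and biweekly PHQ-9
#' self reports.
#'
#' @param subject_id character scalar.
#' @param enrollment epoch milliseconds of enrollment; events before it
#'   are invalid.
#' @param tz_offset_min subject's clock offset, minutes east of UTC.
#' @param accel data.frame(start, stdev_norm): per 2-minute window, the
#'   standard deviation of the gravity-corrected acceleration norm
#'   (m/s^2).
#' @param gps data.frame(t, lat, lon) in degrees.
#' @param wifi data.frame(t, bssids) with `bssids` a `;`-joined list of
#'   access-point identifiers (may be empty).
#' @param comm data.frame(t, kind, direction, contact, duration):
#'   kind in {"call","sms"}, direction in {"in","out"}; duration in
#'   seconds for calls, NA for sms.
#' @param calendar data.frame(t_start, slot) with slot in
#'   {"morning","afternoon","evening"}.
#' @param phoneuse data.frame(t_unlock, t_lock, in_moss_app): unlocked
#'   intervals, with the seconds spent inside the support app recorded so
#'   they can be excluded from phone-use time.
#' @param sessions data.frame(t, interventions_executed).
#' @param phq9 data.frame(t, score) with integer scores in 0..27.
#' @param validate run [validate_subject_stream()] before returning.
#' @return an object of class `subject_stream`.
#' @export
subject_stream <- function(subject_id, enrollment, tz_offset_min = 0,
                           accel = NULL, gps = NULL, wifi = NULL,
                           comm = NULL, calendar = NULL, phoneuse = NULL,
                           sessions = NULL, phq9 = NULL, validate = TRUE) {
  tmpl <- stream_templates()
  fill <- function(x, kind) {
    if (is.null(x) || nrow(x) == 0) return(tmpl[[kind]])
    missing_cols <- setdiff(names(tmpl[[kind]]), names(x))
    if (length(missing_cols))
      stream_error(kind, paste("missing columns:",
                               paste(missing_cols, collapse = ", ")))
    out <- as.data.frame(x)[names(tmpl[[kind]])]
    rownames(out) <- NULL
    out
  }
  s <- structure(
    list(subject_id = as.character(subject_id),
         enrollment = as.numeric(enrollment),
         tz_offset_min = as.numeric(tz_offset_min),
         accel = fill(accel, "accel"), gps = fill(gps, "gps"),
         wifi = fill(wifi, "wifi"), comm = fill(comm, "comm"),
         calendar = fill(calendar, "calendar"),
         phoneuse = fill(phoneuse, "phoneuse"),
         sessions = fill(sessions, "sessions"),
         phq9 = fill(phq9, "phq9")),
    class = "subject_stream")
  if (validate) validate_subject_stream(s)
  s
}

#' Validate a subject stream
#'
#' Checks every structural invariant of the container: per-stream time
#' ordering, events not earlier than enrollment, GPS coordinates within
#' bounds, call-only durations, PHQ-9 scores in 0..27, phone-use
#' intervals positive with in-app time inside them.  Errors name the
#' offending stream and row.
#'
#' @param s a `subject_stream`.
#' @return the stream, invisibly, if valid; otherwise an error.
#' @export
validate_subject_stream <- function(s) {
  stopifnot(inherits(s, "subject_stream"))
  for (kind in STREAM_KINDS) {
    df <- s[[kind]]
    tc <- time_col[[kind]]
    check_sorted(df[[tc]], kind)
    if (nrow(df) && any(df[[tc]] < s$enrollment))
      stream_error(kind, "event before enrollment",
                   row = which(df[[tc]] < s$enrollment)[1])
  }
  g <- s$gps
  if (nrow(g)) {
    bad <- which(g$lat < -90 | g$lat > 90 | g$lon < -180 | g$lon > 180)
    if (length(bad))
      stream_error("gps", sprintf("coordinate out of bounds (lat=%g, lon=%g)",
                                  g$lat[bad[1]], g$lon[bad[1]]), row = bad[1])
  }
  a <- s$accel
  if (nrow(a) && any(a$stdev_norm < 0))
    stream_error("accel", "negative stdev_norm",
                 row = which(a$stdev_norm < 0)[1])
  cm <- s$comm
  if (nrow(cm)) {
    if (!all(cm$kind %in% c("call", "sms")))
      stream_error("comm", "kind must be 'call' or 'sms'",
                   row = which(!cm$kind %in% c("call", "sms"))[1])
    if (!all(cm$direction %in% c("in", "out")))
      stream_error("comm", "direction must be 'in' or 'out'",
                   row = which(!cm$direction %in% c("in", "out"))[1])
    bad <- which(cm$kind == "call" & (is.na(cm$duration) | cm$duration < 0))
    if (length(bad))
      stream_error("comm", "calls need a non-negative duration", row = bad[1])
    bad <- which(cm$kind == "sms" & !is.na(cm$duration))
    if (length(bad))
      stream_error("comm", "sms rows must have NA duration", row = bad[1])
  }
  cal <- s$calendar
  if (nrow(cal) && !all(cal$slot %in% c("morning", "afternoon", "evening")))
    stream_error("calendar", "invalid slot",
                 row = which(!cal$slot %in% c("morning", "afternoon",
                                              "evening"))[1])
  pu <- s$phoneuse
  if (nrow(pu)) {
    bad <- which(pu$t_lock <= pu$t_unlock)
    if (length(bad)) stream_error("phoneuse", "t_lock must exceed t_unlock",
                                  row = bad[1])
    dur_s <- (pu$t_lock - pu$t_unlock) / 1000
    bad <- which(pu$in_moss_app < 0 | pu$in_moss_app > dur_s + 1e-9)
    if (length(bad))
      stream_error("phoneuse", "in_moss_app outside [0, interval length]",
                   row = bad[1])
  }
  q <- s$phq9
  if (nrow(q)) {
    bad <- which(q$score < 0 | q$score > 27 | q$score != round(q$score))
    if (length(bad)) stream_error("phq9", "score must be an integer in 0..27",
                                  row = bad[1])
  }
  ses <- s$sessions
  if (nrow(ses) && any(ses$interventions_executed < 0))
    stream_error("sessions", "negative intervention count",
                 row = which(ses$interventions_executed < 0)[1])
  invisible(s)
}

#' @export
print.subject_stream <- function(x, ...) {
  cat(sprintf("<subject_stream> %s (enrolled %.0f ms, tz %+d min)\n",
              x$subject_id, x$enrollment, as.integer(x$tz_offset_min)))
  for (kind in STREAM_KINDS)
    cat(sprintf("  %-9s %6d events\n", kind, nrow(x[[kind]])))
  invisible(x)
}

#' Write a subject stream to disk
#'
#' The CSV layout is one file per stream kind (`accel.csv`, `gps.csv`,
#' ...) plus `meta.json` holding subject id, enrollment and timezone
#' offset, all inside one directory per subject.  The JSON layout is a
#' single document.  Both round-trip losslessly through
#' [read_subject_stream()].
#'
#' @param s a validated `subject_stream`.
#' @param path directory (csv format) or file path (json format).
#' @param format "csv" or "json".
#' @return `path`, invisibly.
#' @export
write_subject_stream <- function(s, path, format = c("csv", "json")) {
  format <- match.arg(format)
  validate_subject_stream(s)
  if (format == "csv") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(path)) stop("cannot create directory: ", path)
    meta <- list(subject_id = s$subject_id, enrollment = s$enrollment,
                 tz_offset_min = s$tz_offset_min)
    jsonlite::write_json(meta, file.path(path, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
    for (kind in STREAM_KINDS)
      data.table::fwrite(s[[kind]], file.path(path, paste0(kind, ".csv")))
  } else {
    obj <- unclass(s)
    jsonlite::write_json(obj, path, dataframe = "columns", digits = NA,
                         auto_unbox = TRUE, null = "list")
  }
  invisible(path)
}

#' Read a subject stream from disk
#'
#' Inverse of [write_subject_stream()]; the result is validated, and
#' schema problems are reported with the stream name and row number.
#'
#' @param path directory (csv) or file (json) written by
#'   [write_subject_stream()].
#' @param format "csv" or "json".
#' @return a validated `subject_stream`.
#' @export
read_subject_stream <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  tmpl <- stream_templates()
  if (format == "csv") {
    meta_file <- file.path(path, "meta.json")
    if (!file.exists(meta_file)) stop("missing meta.json in ", path)
    meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
    streams <- list()
    for (kind in STREAM_KINDS) {
      f <- file.path(path, paste0(kind, ".csv"))
      if (!file.exists(f)) { streams[[kind]] <- tmpl[[kind]]; next }
      df <- as.data.frame(suppressWarnings(
        data.table::fread(f, colClasses = vapply(
          tmpl[[kind]], function(col) class(col)[1], character(1)))))
      missing_cols <- setdiff(names(tmpl[[kind]]), names(df))
      if (length(missing_cols))
        stream_error(kind, paste("missing mandatory columns:",
                                 paste(missing_cols, collapse = ", ")))
      if (nrow(df) == 0) df <- tmpl[[kind]]
      streams[[kind]] <- df
    }
    if ("wifi" %in% names(streams) && nrow(streams$wifi))
      streams$wifi$bssids[is.na(streams$wifi$bssids)] <- ""
    if (nrow(streams$comm)) streams$comm$duration <-
        suppressWarnings(as.numeric(streams$comm$duration))
    do.call(subject_stream, c(
      list(subject_id = meta$subject_id, enrollment = meta$enrollment,
           tz_offset_min = meta$tz_offset_min), streams))
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    streams <- lapply(STREAM_KINDS, function(kind) {
      df <- obj[[kind]]
      n <- if (is.null(df) || length(df) == 0) 0L else
        max(vapply(df, length, integer(1)))
      if (n == 0) return(tmpl[[kind]])
      df <- as.data.frame(df)
      if (kind == "comm") {
        if (!"duration" %in% names(df))
          df$duration <- rep(NA_real_, nrow(df))
        df$duration <- suppressWarnings(as.numeric(df$duration))
      }
      df
    })
    names(streams) <- STREAM_KINDS
    do.call(subject_stream, c(
      list(subject_id = obj$subject_id, enrollment = obj$enrollment,
           tz_offset_min = obj$tz_offset_min), streams))
  }
}
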