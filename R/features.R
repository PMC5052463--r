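# Behavioral proxy features computed from one subject's sensor streams:
# accelerometer-based general activity and walking time, WiFi-fingerprint
# time at home, GPS mobility metrics (maximum / total distance and the
# log location variance), phone use, and communication / calendar counts.

#' Canonical base-feature roster
#'
#' The 24 per-day behavioral features over which descriptive statistics
#' are taken.  The first 18 are measured directly; the final 6 are
#' derived totals and ratios (the roster is a documented package choice,
#' fixed so that downstream vectors have a stable 24 x 5 = 120 layout).
#'
#' @return character vector of length 24.
#' @export
base_feature_names <- function() {
  c("general_activity", "walking_min", "time_at_home_min", "phone_use_min",
    "max_dist_m", "total_dist_m", "loc_var", "n_unique_wifi",
    "sms_in", "sms_out", "sms_unique_contacts",
    "calls_in", "calls_out", "calls_unique_contacts", "avg_call_duration_s",
    "cal_morning", "cal_afternoon", "cal_evening",
    "sms_total", "calls_total", "comm_unique_contacts_total", "cal_total",
    "dist_per_fix", "home_fraction")
}

#' General activity from one window of raw accelerometer samples
#'
#' The standard deviation of the gravity-corrected Euclidean norm of the
#' tri-axial acceleration over a window:
#' `sd(sqrt(ax^2 + ay^2 + az^2) - 9.81)`.  Subtracting the constant
#' gravity term leaves the dispersion unchanged; it is kept for fidelity
#' to the published form.  The statistic depends on the samples only
#' through their norms, so it is invariant to any rotation of the axis
#' frame.
#'
#' @param samples matrix or data.frame with columns `ax`, `ay`, `az`
#'   (m/s^2); nominally 100 Hz per axis, i.e. 300 scalar samples per
#'   second of window.
#' @param gravity gravity constant subtracted from the norm (m/s^2).
#' @return non-negative scalar (m/s^2); sample standard deviation.
#' @export
#' @examples
#' activity_stdev(data.frame(ax = 0, ay = 0, az = c(9.81, 9.81)))  # 0
activity_stdev <- function(samples, gravity = 9.81) {
  samples <- as.data.frame(samples)
  if (!all(c("ax", "ay", "az") %in% names(samples)))
    stop("samples need columns ax, ay, az", call. = FALSE)
  if (nrow(samples) < 2)
    stop("insufficient data: need at least 2 samples", call. = FALSE)
  norms <- sqrt(samples$ax^2 + samples$ay^2 + samples$az^2) - gravity
  stats::sd(norms)
}

#' Walking classification of an activity window
#'
#' A 2-minute window counts as walking when its activity dispersion
#' reaches the intensity threshold (1.5 m/s^2, boundary inclusive).
#'
#' @param stdev_norm non-negative numeric vector of window statistics.
#' @param threshold walking threshold (m/s^2).
#' @return logical vector.
#' @export
classify_walking <- function(stdev_norm, threshold = 1.5) {
  if (any(is.na(stdev_norm)) || any(stdev_norm < 0))
    stop("stdev_norm must be non-negative", call. = FALSE)
  stdev_norm >= threshold
}

#' Great-circle distance (haversine)
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees (vectorized).
#' @param radius_m Earth radius in meters (spherical model).
#' @return distance(s) in meters.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2, radius_m = 6371000) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * radius_m * asin(pmin(1, sqrt(a)))
}

#' Daily GPS mobility metrics
#'
#' Total distance is the sum of consecutive-fix great-circle distances;
#' maximum distance is the largest pairwise great-circle distance; the
#' location variance is `log(var(lat) + var(lon))` on raw degree
#' coordinates (population variances, natural log), floored at
#' `log(floor_deg2)` for degenerate days so the statistic is defined
#' when the subject never moves.
#'
#' @param fixes data.frame(t, lat, lon), one day of fixes.
#' @param floor_deg2 variance floor in degrees^2.
#' @return list(max_dist_m, total_dist_m, loc_var, n_fixes).
#' @export
gps_metrics <- function(fixes, floor_deg2 = 1e-12) {
  n <- nrow(fixes)
  if (n == 0) stop("need at least one fix", call. = FALSE)
  if (n == 1)
    return(list(max_dist_m = 0, total_dist_m = 0, loc_var = NA_real_,
                n_fixes = 1L))
  total <- sum(haversine_m(fixes$lat[-n], fixes$lon[-n],
                           fixes$lat[-1], fixes$lon[-1]))
  ij <- utils::combn(n, 2)
  maxd <- max(haversine_m(fixes$lat[ij[1, ]], fixes$lon[ij[1, ]],
                          fixes$lat[ij[2, ]], fixes$lon[ij[2, ]]))
  v <- pop_var(fixes$lat) + pop_var(fixes$lon)
  list(max_dist_m = maxd, total_dist_m = total,
       loc_var = log(max(v, floor_deg2)), n_fixes = n)
}

#' Learn a home WiFi fingerprint from night scans
#'
#' Nightly BSSID sets (the union of all scans inside the configured night
#' window) are compared across the first three consecutive nights; if all
#' pairwise Jaccard overlaps reach `jaccard_min` ("reasonable overlap"),
#' the intersection of the three sets becomes the home fingerprint.
#' Absence of such a triple is a valid outcome (`NULL`), standing in for
#' the app falling back to asking the user.
#'
#' @param wifi data.frame(t, bssids) of scans.
#' @param tz_offset_min subject clock offset in minutes.
#' @param night_hours half-open local-hour window counting as night.
#' @param jaccard_min minimal pairwise Jaccard overlap.
#' @return a `home_fingerprint` (list with `bssids`, `learned_at`,
#'   `confirmed`) or `NULL`.
#' @export
learn_home <- function(wifi, tz_offset_min = 0, night_hours = c(0, 5),
                       jaccard_min = 0.5) {
  if (nrow(wifi) == 0) return(NULL)
  hr <- ms_hour(wifi$t, tz_offset_min)
  night <- hr >= night_hours[1] & hr < night_hours[2]
  if (!any(night)) return(NULL)
  nw <- wifi[night, ]
  nights <- split(nw, ms_day(nw$t, tz_offset_min))
  sets <- lapply(nights, function(df)
    unique(unlist(lapply(df$bssids, split_bssids))))
  day_ids <- as.integer(names(nights))
  jac <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0) 0 else length(intersect(a, b)) / u
  }
  if (length(day_ids) < 3) return(NULL)
  for (i in seq_len(length(day_ids) - 2)) {
    if (day_ids[i + 1] != day_ids[i] + 1 || day_ids[i + 2] != day_ids[i] + 2)
      next
    a <- sets[[i]]; b <- sets[[i + 1]]; c3 <- sets[[i + 2]]
    if (jac(a, b) >= jaccard_min && jac(a, c3) >= jaccard_min &&
        jac(b, c3) >= jaccard_min) {
      fp <- Reduce(intersect, list(a, b, c3))
      if (length(fp) == 0) next
      return(structure(list(bssids = sort(fp),
                            learned_at = max(nights[[i + 2]]$t),
                            confirmed = TRUE),
                       class = "home_fingerprint"))
    }
  }
  NULL
}

# does one scan match the home fingerprint?  rule "any": non-empty
# intersection; rule "fraction": at least min_frac of the fingerprint seen
scan_at_home <- function(bssids_str, home, rule = c("any", "fraction"),
                         min_frac = 0.5) {
  rule <- match.arg(rule)
  seen <- split_bssids(bssids_str)
  hit <- length(intersect(seen, home$bssids))
  if (rule == "any") hit > 0 else hit >= min_frac * length(home$bssids)
}

# slice helper: events of one local day
.day_slice <- function(df, tcol, day, tz) {
  df[ms_day(df[[tcol]], tz) == day, , drop = FALSE]
}

#' Base behavioral features for one calendar day
#'
#' Populates every per-day feature from the day's events.  Time at home
#' is 15 minutes per WiFi scan matching the home fingerprint; walking is
#' 2 minutes per window at or above the walking threshold; phone use
#' excludes time spent inside the support app.  Sensors absent on the day
#' yield zero values flagged in a per-feature missingness mask
#' (`<name>__mask` columns, `TRUE` = missing): continuous sensors
#' (accelerometer, GPS, WiFi, phone state) are considered missing when no
#' events exist on the day, while event logs (communication, calendar)
#' are missing only when the subject-level stream is entirely empty —
#' a silent phone is data, an unlogged phone is not.  A day with no
#' events in any stream is treated as unobserved and fully masked.
#' Without a home fingerprint, time at home is flagged missing, not
#' zero.
#'
#' @param stream a validated `subject_stream`.
#' @param date local day: a `Date`, or an integer day index (days since
#'   1970-01-01 on the subject's clock).
#' @param home a `home_fingerprint` from [learn_home()], or `NULL`.
#' @param walking_threshold m/s^2, see [classify_walking()].
#' @param home_rule scan-to-fingerprint match rule, see details of
#'   [learn_home()].
#' @return one-row data.frame: `date`, the 24 base features of
#'   [base_feature_names()], and one logical `__mask` column per feature.
#' @export
daily_base_features <- function(stream, date, home = NULL,
                                walking_threshold = 1.5,
                                home_rule = "any") {
  tz <- stream$tz_offset_min
  day <- if (inherits(date, "Date")) as.integer(unclass(date)) else
    as.integer(date)
  v <- stats::setNames(numeric(24), base_feature_names())
  m <- stats::setNames(rep(FALSE, 24), base_feature_names())

  # accelerometer windows
  aw <- .day_slice(stream$accel, "start", day, tz)
  if (nrow(aw) == 0) {
    m[c("general_activity", "walking_min")] <- TRUE
  } else {
    v["general_activity"] <- mean(aw$stdev_norm)
    v["walking_min"] <- 2 * sum(classify_walking(aw$stdev_norm,
                                                 walking_threshold))
  }

  # gps
  gf <- .day_slice(stream$gps, "t", day, tz)
  if (nrow(gf) == 0) {
    m[c("max_dist_m", "total_dist_m", "loc_var", "dist_per_fix")] <- TRUE
  } else {
    gm <- gps_metrics(gf)
    v["max_dist_m"] <- gm$max_dist_m
    v["total_dist_m"] <- gm$total_dist_m
    if (is.na(gm$loc_var)) m["loc_var"] <- TRUE else v["loc_var"] <- gm$loc_var
    v["dist_per_fix"] <- gm$total_dist_m / gm$n_fixes
  }

  # wifi
  ws <- .day_slice(stream$wifi, "t", day, tz)
  if (nrow(ws) == 0) {
    m[c("n_unique_wifi", "time_at_home_min", "home_fraction")] <- TRUE
  } else {
    v["n_unique_wifi"] <- length(unique(unlist(lapply(ws$bssids,
                                                      split_bssids))))
    if (is.null(home)) {
      m[c("time_at_home_min", "home_fraction")] <- TRUE
    } else {
      hits <- vapply(ws$bssids, scan_at_home, logical(1), home = home,
                     rule = home_rule)
      v["time_at_home_min"] <- 15 * sum(hits)
      v["home_fraction"] <- v["time_at_home_min"] / 1440
    }
  }

  # phone use (minutes unlocked, in-app time excluded pro rata)
  pu <- stream$phoneuse
  d0 <- day_start_ms(day, tz); d1 <- d0 + MS_PER_DAY
  if (nrow(pu)) {
    ov <- pmin(pu$t_lock, d1) - pmax(pu$t_unlock, d0)
    keep <- ov > 0
    if (any(keep)) {
      frac <- ov[keep] / (pu$t_lock[keep] - pu$t_unlock[keep])
      mins <- ov[keep] / MS_PER_MIN - frac * pu$in_moss_app[keep] / 60
      v["phone_use_min"] <- max(0, sum(mins))
    } else m["phone_use_min"] <- TRUE
  } else m["phone_use_min"] <- TRUE

  # communication (event log: missing only if never recorded at all)
  cm <- stream$comm
  if (nrow(cm) == 0) {
    m[c("sms_in", "sms_out", "sms_unique_contacts", "calls_in", "calls_out",
        "calls_unique_contacts", "avg_call_duration_s", "sms_total",
        "calls_total", "comm_unique_contacts_total")] <- TRUE
  } else {
    cd <- .day_slice(cm, "t", day, tz)
    sms <- cd[cd$kind == "sms", ]; cal <- cd[cd$kind == "call", ]
    v["sms_in"] <- sum(sms$direction == "in")
    v["sms_out"] <- sum(sms$direction == "out")
    v["sms_unique_contacts"] <- length(unique(sms$contact))
    v["calls_in"] <- sum(cal$direction == "in")
    v["calls_out"] <- sum(cal$direction == "out")
    v["calls_unique_contacts"] <- length(unique(cal$contact))
    v["sms_total"] <- nrow(sms)
    v["calls_total"] <- nrow(cal)
    v["comm_unique_contacts_total"] <- length(unique(cd$contact))
    if (nrow(cal)) {
      v["avg_call_duration_s"] <- mean(cal$duration)
    } else m["avg_call_duration_s"] <- TRUE  # zero calls: no duration defined
  }

  # calendar (event log)
  ce <- stream$calendar
  if (nrow(ce) == 0) {
    m[c("cal_morning", "cal_afternoon", "cal_evening", "cal_total")] <- TRUE
  } else {
    cd <- .day_slice(ce, "t_start", day, tz)
    v["cal_morning"] <- sum(cd$slot == "morning")
    v["cal_afternoon"] <- sum(cd$slot == "afternoon")
    v["cal_evening"] <- sum(cd$slot == "evening")
    v["cal_total"] <- nrow(cd)
  }

  # a day with no events in any stream is unobserved, not quiet: mask all
  n_events <- nrow(aw) + nrow(gf) + nrow(ws) +
    nrow(.day_slice(stream$comm, "t", day, tz)) +
    nrow(.day_slice(stream$calendar, "t_start", day, tz)) +
    sum(pmin(stream$phoneuse$t_lock, d1) >
          pmax(stream$phoneuse$t_unlock, d0))
  if (n_events == 0) m[] <- TRUE

  out <- data.frame(date = as.Date(day, origin = "1970-01-01"))
  out[base_feature_names()] <- as.list(v)
  out[paste0(base_feature_names(), "__mask")] <- as.list(m)
  out
}

#' Per-day feature table for a whole subject
#'
#' Runs [learn_home()] once and [daily_base_features()] for every local
#' day in the stream's span.
#'
#' @param stream a validated `subject_stream`.
#' @param home optional precomputed `home_fingerprint`; learned from the
#'   stream when missing.
#' @param ... passed to [daily_base_features()].
#' @return data.frame, one row per calendar day, with a
#'   `subject_id` column prepended.
#' @export
extract_day_features <- function(stream, home = learn_home(
                                   stream$wifi, stream$tz_offset_min),
                                 ...) {
  tz <- stream$tz_offset_min
  all_t <- c(stream$accel$start, stream$gps$t, stream$wifi$t, stream$comm$t,
             stream$calendar$t_start, stream$phoneuse$t_unlock,
             stream$sessions$t, stream$phq9$t)
  if (length(all_t) == 0)
    stop("stream contains no events", call. = FALSE)
  days <- seq(ms_day(min(all_t), tz), ms_day(max(all_t), tz))
  rows <- lapply(days, function(d)
    daily_base_features(stream, d, home = home, ...))
  out <- do.call(rbind, rows)
  cbind(subject_id = stream$subject_id, out)
}
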