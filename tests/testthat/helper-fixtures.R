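# Shared fixtures, all built in code at test time.

DAY0 <- 1425168000000  # 2015-03-01 00:00 UTC, day index 16495
DAY0_IDX <- 16495L

# a small hand-built stream covering two days with known event counts
make_tiny_stream <- function() {
  d0 <- DAY0
  hr <- 3600000
  subject_stream(
    subject_id = "T1", enrollment = d0,
    accel = data.frame(start = d0 + 8 * hr + (0:9) * 120000,
                       stdev_norm = c(2, 2, 0.3, 0.3, 1.5, 0.2, 0.2, 0.2,
                                      1.7, 0.1)),
    gps = data.frame(t = d0 + c(9, 10, 11) * hr,
                     lat = c(47.37, 47.38, 47.37),
                     lon = c(8.54, 8.54, 8.55)),
    wifi = data.frame(t = d0 + c(1, 2, 9, 12) * hr,
                      bssids = c("H1;H2", "H1;H2", "H1;X1", "X2;X3")),
    comm = data.frame(
      t = d0 + c(9.5, 10.5, 11.5, 13) * hr,
      kind = c("call", "sms", "sms", "call"),
      direction = c("in", "out", "out", "out"),
      contact = c("A", "B", "A", "A"),
      duration = c(60, NA, NA, 180)),
    calendar = data.frame(t_start = d0 + c(9, 14, 20) * hr,
                          slot = c("morning", "afternoon", "evening")),
    phoneuse = data.frame(t_unlock = d0 + c(8, 20) * hr,
                          t_lock = d0 + c(8.5, 20.25) * hr,
                          in_moss_app = c(300, 0)),
    sessions = data.frame(t = d0 + c(10, 18) * hr,
                          interventions_executed = c(0L, 2L)),
    phq9 = data.frame(t = d0 + 12 * hr, score = 12L))
}

# home fingerprint matching the tiny stream's night scans
tiny_home <- function() {
  structure(list(bssids = c("H1", "H2"), learned_at = DAY0 + 2 * 3600000,
                 confirmed = TRUE), class = "home_fingerprint")
}

# a minimal cohort_table-shaped data.frame built from explicit PHQ-9
# series; `series` is a list of integer vectors (baseline first),
# `sessions` a vector of qualifying session counts
make_cohort <- function(series, sessions = NULL,
                        adherence_weeks = NULL) {
  n <- length(series)
  if (is.null(sessions)) sessions <- rep(10L, n)
  if (is.null(adherence_weeks))
    adherence_weeks <- vapply(series, function(s) 2 * (length(s) - 1),
                              numeric(1))
  out <- data.frame(
    subject_id = sprintf("P%02d", seq_len(n)),
    enrollment = DAY0, last_activity = DAY0,
    adherence_weeks = adherence_weeks,
    baseline_phq9 = vapply(series, `[`, numeric(1), 1),
    n_post_baseline = vapply(series, function(s) length(s) - 1L,
                             integer(1)),
    sessions_total = sessions)
  out$phq9 <- lapply(series, function(s)
    data.frame(t = DAY0 + seq_along(s) * 14 * 86400000, score = s))
  class(out) <- c("cohort_table", "data.frame")
  out
}

# 14 day-feature rows with every base feature constant at `value`
# except those supplied in `override` (a named list of length-14
# vectors); masks all FALSE unless listed in `mask` (named list)
make_day_table <- function(value = 1, override = list(), mask = list()) {
  days <- as.Date(DAY0_IDX:(DAY0_IDX + 13), origin = "1970-01-01")
  out <- data.frame(date = days)
  for (b in base_feature_names()) {
    out[[b]] <- if (b %in% names(override)) override[[b]] else
      rep(value, 14)
    mcol <- paste0(b, "__mask")
    out[[mcol]] <- if (b %in% names(mask)) mask[[b]] else rep(FALSE, 14)
  }
  out
}

# random proper rotation matrix (Haar-ish via QR)
random_rotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qrd)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
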