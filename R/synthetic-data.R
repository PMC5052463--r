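# Simulation of multi-week sensor streams whose behavioral statistics are
# coupled to a latent depression-severity trajectory on the PHQ-9 scale.
#
# The generative model is deliberately simple and fully stated: severity
# maps linearly between two behavioral anchor points (the "weakly" and
# "strongly pronounced" daily magnitudes assumed for the general depressed
# population: time at home spanning under 7 to over 14 h/day, calls 0 to
# over 6/day, walking under 30 to over 300 min/day), day-level Gaussian
# noise is added on top, and every stream is emitted in the canonical
# subject_stream layout.  Ground truth (per-day behavioral targets, the
# home fingerprint, the severity trajectory) travels with the stream as an
# attribute so oracle tests can check recovery.

# anchor values at severity 0 (healthy end) and severity 27 (severe end)
default_behavior_coefs <- function() {
  list(
    home_h     = c(6, 15),    # h/day at home: brackets <7 .. >14
    walk_min   = c(320, 25),  # min/day walking: brackets >300 .. <30
    calls      = c(7, 0),     # calls/day: brackets >6 .. 0
    texts      = c(9, 1),     # sms/day (anchor invented, same direction)
    loc_spread = c(0.05, 0.005), # degrees of away-excursion spread
    phone_h    = c(2.0, 4.5), # phone use rises with severity
    cal_events = c(3, 0.5)    # calendar events/day
  )
}

#' Expected daily behavior for a given severity
#'
#' Linear interpolation between the healthy (severity 0) and severe
#' (severity 27) anchors, optionally shrunk toward the healthy end by an
#' effect-size multiplier.  This is the noiseless mean structure of the
#' simulator; monotone-coupling properties are asserted against it.
#'
#' @param severity PHQ-9-scale value(s) in 0..27.
#' @param coefs anchor list as from `default_behavior_coefs()`.
#' @param effect multiplier on the healthy-to-severe contrast (1 = stated
#'   anchors, 0 = severity has no behavioral effect).
#' @return a data.frame with one row per severity value and one column
#'   per behavior (home_h, walk_min, calls, texts, loc_spread, phone_h,
#'   cal_events).
#' @export
behavior_means <- function(severity, coefs = default_behavior_coefs(),
                           effect = 1) {
  stopifnot(all(is.finite(severity)), severity >= 0, severity <= 27)
  frac <- severity / 27
  out <- lapply(coefs, function(a) a[1] + effect * frac * (a[2] - a[1]))
  as.data.frame(out)
}

#' Simulation profile for one subject
#'
#' @param subject_id character id.
#' @param severity numeric vector of latent PHQ-9-scale values, one per
#'   2-week epoch; the stream spans `2 * length(severity)` weeks and
#'   carries `length(severity) + 1` PHQ-9 records (baseline plus one per
#'   epoch end).
#' @param coefs behavioral anchors, see [behavior_means()].
#' @param effect severity-to-behavior effect multiplier.
#' @param noise day-level behavioral noise scale (0 = deterministic
#'   behavior, 1 = default realistic scatter).
#' @param phq9_sd standard deviation of the discretized Gaussian PHQ-9
#'   observation noise, in questionnaire points.
#' @param enrollment epoch ms of day 0 (default 2015-03-01 00:00 UTC).
#' @param seed integer RNG seed for this subject.
#' @return a `sim_profile` list.
#' @export
sim_profile <- function(subject_id = "S1", severity = c(12, 12, 12),
                        coefs = default_behavior_coefs(), effect = 1,
                        noise = 1, phq9_sd = 2,
                        enrollment = 1425168000000, seed = 1L) {
  if (!all(vapply(coefs, function(x) all(is.finite(x)), logical(1))))
    stop("non-finite behavior coefficients", call. = FALSE)
  stopifnot(length(severity) >= 1, all(severity >= 0), all(severity <= 27),
            is.finite(effect), noise >= 0, phq9_sd >= 0)
  structure(list(subject_id = as.character(subject_id),
                 severity = as.numeric(severity), coefs = coefs,
                 effect = effect, noise = noise, phq9_sd = phq9_sd,
                 enrollment = as.numeric(enrollment),
                 seed = as.integer(seed)),
            class = "sim_profile")
}

# day-level noise scales (units of each behavior), multiplied by `noise`
.day_noise_sd <- list(home_slots = 4, walk_min = 25, calls = 1.5,
                      texts = 2.5, phone_min = 30, cal_events = 0.8,
                      gps_jitter_deg = 2e-4)

#' Simulate one subject's sensor record
#'
#' Emits 2-minute activity windows over the waking day, WiFi scans and
#' GPS fixes at a 15-minute cadence, call/SMS logs, calendar events,
#' phone-use intervals, app sessions and biweekly PHQ-9 records, all
#' driven by the profile's severity trajectory.  Nights (00:00-05:00) are
#' always spent at the subject's home WiFi fingerprint so home learning
#' has its three consecutive nights.  With `noise = 0` the realized daily
#' time at home, walking minutes and call counts equal their generator
#' targets exactly; the targets are attached as `attr(, "truth")`.
#'
#' @param profile a [sim_profile()].
#' @return a validated `subject_stream` with a `truth` attribute:
#'   `severity`, `home_bssids`, `day` (per-day behavioral targets),
#'   `qualifying_sessions`, `phq9_true`.
#' @export
simulate_subject <- function(profile) {
  stopifnot(inherits(profile, "sim_profile"))
  set.seed(profile$seed)
  n_epochs <- length(profile$severity)
  n_days <- 14L * n_epochs
  t0 <- profile$enrollment
  home_bssids <- paste0("HOME_", profile$subject_id, "_", 1:3)
  ap_pool <- paste0("AP_", sprintf("%03d", 1:150))
  contacts <- paste0("C", 1:10)
  home_lat <- 47.3769 + runif(1, -0.05, 0.05)
  home_lon <- 8.5417 + runif(1, -0.05, 0.05)
  ns <- profile$noise

  accel <- vector("list", n_days); gps <- vector("list", n_days)
  wifi <- vector("list", n_days); comm <- vector("list", n_days)
  calendar <- vector("list", n_days); phoneuse <- vector("list", n_days)
  sessions <- vector("list", n_days)
  truth_day <- vector("list", n_days)

  for (d in seq_len(n_days) - 1L) {
    epoch <- d %/% 14L + 1L
    mu <- behavior_means(profile$severity[epoch], profile$coefs,
                         profile$effect)
    day0 <- t0 + d * MS_PER_DAY

    # --- at-home structure: k of 96 fifteen-minute slots, anchored to the
    # night so the front of the day and the late evening are at home
    k <- round(mu$home_h * 4 + ns * .day_noise_sd$home_slots * rnorm(1))
    k <- max(21L, min(96L, as.integer(k)))  # >= 21 keeps nights at home
    front <- min(k, 48L)
    at_home <- c(rep(TRUE, front), rep(FALSE, 96L - k),
                 rep(TRUE, k - front))

    # --- wifi scans every 15 min
    scan_t <- day0 + (0:95) * 15 * MS_PER_MIN
    away_aps <- vapply(seq_len(96), function(i) {
      if (at_home[i]) join_bssids(home_bssids)
      else join_bssids(sample(ap_pool, sample(1:3, 1)))
    }, character(1))
    wifi[[d + 1L]] <- data.frame(t = scan_t, bssids = away_aps)

    # --- gps fixes every 15 min, 30 s after the scan
    spread <- mu$loc_spread
    jit <- ns * .day_noise_sd$gps_jitter_deg
    lat <- ifelse(at_home, home_lat + jit * rnorm(96),
                  home_lat + spread * rnorm(96))
    lon <- ifelse(at_home, home_lon + jit * rnorm(96),
                  home_lon + spread * rnorm(96))
    gps[[d + 1L]] <- data.frame(t = scan_t + 30000, lat = lat, lon = lon)

    # --- activity windows over the waking day [07:00, 23:00): 480 windows
    w_start <- day0 + 7 * 3600000 + (0:479) * 2 * MS_PER_MIN
    n_walk <- round(mu$walk_min / 2 + ns * .day_noise_sd$walk_min / 2 * rnorm(1))
    n_walk <- max(0L, min(480L, as.integer(n_walk)))
    sd_norm <- pmin(abs(rnorm(480, 0.25, ns * 0.1)), 1.4)
    if (n_walk > 0) {
      walk_idx <- sample.int(480, n_walk)
      sd_norm[walk_idx] <- 2 + ns * abs(rnorm(n_walk, 0, 0.3))
    }
    accel[[d + 1L]] <- data.frame(start = w_start, stdev_norm = sd_norm)

    # --- communication events
    n_calls <- max(0L, as.integer(round(mu$calls + ns * .day_noise_sd$calls *
                                          rnorm(1))))
    n_texts <- max(0L, as.integer(round(mu$texts + ns * .day_noise_sd$texts *
                                          rnorm(1))))
    n_comm <- n_calls + n_texts
    if (n_comm > 0) {
      ct <- sort(day0 + 8 * 3600000 + runif(n_comm, 0, 14 * 3600000))
      kindv <- sample(c(rep("call", n_calls), rep("sms", n_texts)))
      comm[[d + 1L]] <- data.frame(
        t = ct, kind = kindv,
        direction = sample(c("in", "out"), n_comm, replace = TRUE),
        contact = sample(contacts, n_comm, replace = TRUE),
        duration = ifelse(kindv == "call",
                          round(pmax(10, 120 + ns * 60 * rnorm(n_comm))),
                          NA_real_))
    }

    # --- calendar events
    n_cal <- max(0L, as.integer(round(mu$cal_events +
                                        ns * .day_noise_sd$cal_events *
                                        rnorm(1))))
    if (n_cal > 0) {
      hours <- runif(n_cal, 6, 23.5)
      calendar[[d + 1L]] <- data.frame(
        t_start = sort(day0 + hours * 3600000),
        slot = day_slot(sort(hours)))
    }

    # --- phone use: four unlocked intervals spread over the day
    total_min <- max(20, mu$phone_h * 60 + ns * .day_noise_sd$phone_min *
                       rnorm(1))
    piece <- total_min / 4
    starts <- day0 + c(8, 12, 17, 21) * 3600000
    moss_s <- c(120, 0, 0, 60)  # in-app seconds, excluded from phone use
    phoneuse[[d + 1L]] <- data.frame(
      t_unlock = starts,
      t_lock = starts + piece * MS_PER_MIN,
      in_moss_app = pmin(moss_s, piece * 60))

    # --- app sessions (one or two per day; some execute no intervention)
    n_ses <- sample(1:2, 1)
    sessions[[d + 1L]] <- data.frame(
      t = day0 + sort(runif(n_ses, 9, 22)) * 3600000,
      interventions_executed = sample(0:2, n_ses, replace = TRUE))

    truth_day[[d + 1L]] <- data.frame(
      day = d, severity = profile$severity[epoch],
      time_at_home_min = 15 * k, walking_min = 2 * n_walk,
      calls = n_calls, texts = n_texts)
  }

  # --- biweekly PHQ-9: baseline + one record just after each epoch end,
  # so the 14 sensed days of the epoch are exactly the window before it
  phq_t <- t0 + c(60000, (seq_len(n_epochs) * 14) * MS_PER_DAY + 60000)
  phq_true <- c(profile$severity[1], profile$severity)
  phq_obs <- as.integer(pmin(27, pmax(0, round(
    phq_true + profile$phq9_sd * rnorm(length(phq_true))))))

  s <- subject_stream(
    subject_id = profile$subject_id, enrollment = t0,
    accel = do.call(rbind, accel), gps = do.call(rbind, gps),
    wifi = do.call(rbind, wifi),
    comm = {
      cm <- do.call(rbind, comm)
      if (!is.null(cm)) cm[order(cm$t), ] else NULL
    },
    calendar = do.call(rbind, calendar),
    phoneuse = do.call(rbind, phoneuse),
    sessions = do.call(rbind, sessions),
    phq9 = data.frame(t = phq_t, score = phq_obs))

  truth_day <- do.call(rbind, truth_day)
  attr(s, "truth") <- list(
    severity = profile$severity, home_bssids = home_bssids,
    home_coords = c(lat = home_lat, lon = home_lon),
    day = truth_day, phq9_true = phq_true,
    qualifying_sessions = sum(s$sessions$interventions_executed >= 1))
  s
}

#' Cohort simulation configuration
#'
#' @param n_subjects number of subjects (>= 1).
#' @param weeks weeks of potential follow-up per subject (multiple of 2).
#' @param dropout_hazard probability of dropping out after each completed
#'   2-week epoch (every subject completes the baseline epoch).
#' @param frac_ge11 fraction of subjects whose baseline severity is in the
#'   clinically relevant range (PHQ-9 >= 11).
#' @param effect,noise,phq9_sd passed to [sim_profile()].
#' @param seed global seed; per-subject seeds are derived from it.
#' @return a `sim_cohort_config` list.
#' @export
sim_cohort_config <- function(n_subjects = 20, weeks = 6,
                              dropout_hazard = 0, frac_ge11 = 0.5,
                              effect = 1, noise = 1, phq9_sd = 2,
                              seed = 1L) {
  stopifnot(n_subjects >= 1, weeks >= 2, weeks %% 2 == 0,
            dropout_hazard >= 0, dropout_hazard <= 1,
            frac_ge11 >= 0, frac_ge11 <= 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 weeks = as.integer(weeks),
                 dropout_hazard = dropout_hazard, frac_ge11 = frac_ge11,
                 effect = effect, noise = noise, phq9_sd = phq9_sd,
                 seed = as.integer(seed)),
            class = "sim_cohort_config")
}

#' Simulate a cohort of subjects
#'
#' Baseline severities are drawn uniformly from 12..22 for the clinical
#' fraction and 2..9 otherwise, then follow a small random walk across
#' epochs.  Dropout is applied epoch-wise: after each completed 2-week
#' epoch a subject leaves with probability `dropout_hazard`; all events
#' before dropout are retained.
#'
#' @param config a [sim_cohort_config()].
#' @return list of `subject_stream`s; `attr(, "truth")` holds a per
#'   subject summary (baseline severity, epochs completed, home bssids).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  max_epochs <- config$weeks %/% 2L
  is_clin <- seq_len(n) <= round(config$frac_ge11 * n)
  base_sev <- ifelse(is_clin, sample(12:22, n, replace = TRUE),
                     sample(2:9, n, replace = TRUE))
  # epochs completed: baseline epoch guaranteed, then geometric survival
  epochs <- rep(1L, n)
  for (i in seq_len(n)) {
    while (epochs[i] < max_epochs &&
           runif(1) >= config$dropout_hazard) {
      epochs[i] <- epochs[i] + 1L
    }
  }
  sub_seeds <- sample.int(2^31 - 2, n)

  streams <- vector("list", n)
  for (i in seq_len(n)) {
    sev <- numeric(epochs[i])
    sev[1] <- base_sev[i]
    if (epochs[i] > 1) {
      for (e in 2:epochs[i])
        sev[e] <- min(27, max(0, sev[e - 1] + sample(-2:2, 1)))
    }
    prof <- sim_profile(subject_id = sprintf("S%03d", i), severity = sev,
                        effect = config$effect, noise = config$noise,
                        phq9_sd = config$phq9_sd, seed = sub_seeds[i])
    streams[[i]] <- simulate_subject(prof)
  }
  attr(streams, "truth") <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    baseline_severity = base_sev, epochs_completed = epochs,
    clinical_baseline = is_clin)
  streams
}

#' Write a simulated cohort to a directory
#'
#' One CSV-set subdirectory per subject plus `truth.json` holding the
#' simulator's ground truth (severities, home fingerprints, dropout).
#'
#' @param streams output of [simulate_cohort()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(streams, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth_all <- list()
  for (s in streams) {
    write_subject_stream(s, file.path(dir, s$subject_id), format = "csv")
    tr <- attr(s, "truth")
    truth_all[[s$subject_id]] <- list(
      severity = tr$severity, home_bssids = tr$home_bssids,
      phq9_true = tr$phq9_true,
      qualifying_sessions = tr$qualifying_sessions)
  }
  jsonlite::write_json(truth_all, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing per-subject CSV sets.
#' @return list of `subject_stream`s (without truth attributes).
#' @export
read_cohort <- function(dir) {
  subs <- list.dirs(dir, recursive = FALSE)
  streams <- lapply(subs, read_subject_stream, format = "csv")
  streams[order(vapply(streams, function(s) s$subject_id, character(1)))]
}
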