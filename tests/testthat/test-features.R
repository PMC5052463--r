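test_that("activity dispersion follows the window-statistic definition", {
  # 100 Hz tri-axial over a 2-minute window: 12000 rows, 3 scalar
  # samples each -> 300 scalar samples consumed per second
  n <- 120 * 100
  win <- data.frame(ax = rnorm(n), ay = rnorm(n), az = rnorm(n))
  expect_equal(nrow(win) * 3 / 120, 300)
  expect_gte(activity_stdev(win), 0)

  # constant norm: zero dispersion
  expect_equal(activity_stdev(data.frame(ax = 0, ay = 0,
                                         az = rep(9.81, 10))), 0)

  # norms alternating 9.81 +/- 1: oracle is the direct two-point sample
  # standard deviation of {+1, -1}
  m <- 50
  alt <- data.frame(ax = 0, ay = 0, az = rep(c(10.81, 8.81), m))
  oracle <- stats::sd(rep(c(1, -1), m))
  expect_equal(activity_stdev(alt), oracle)

  expect_error(activity_stdev(data.frame(ax = 1, ay = 1, az = 1)),
               "insufficient")
})

test_that("activity dispersion is invariant under frame rotations", {
  set.seed(42)
  base <- matrix(rnorm(300, sd = 2), ncol = 3)
  ref <- activity_stdev(data.frame(ax = base[, 1], ay = base[, 2],
                                   az = base[, 3]))
  for (i in 1:5) {
    R <- random_rotation()
    rot <- base %*% t(R)
    expect_equal(activity_stdev(data.frame(ax = rot[, 1], ay = rot[, 2],
                                           az = rot[, 3])),
                 ref, tolerance = 1e-10)
  }
})

test_that("walking classification uses an inclusive 1.5 threshold", {
  expect_true(classify_walking(1.6))
  expect_false(classify_walking(1.4))
  expect_true(classify_walking(1.5))       # boundary convention
  expect_identical(classify_walking(c(0, 2, 1.5)), c(FALSE, TRUE, TRUE))
  expect_true(classify_walking(1.0, threshold = 0.9))
  expect_error(classify_walking(-0.1), "non-negative")
})

test_that("home learning needs three overlapping consecutive nights", {
  night <- function(day, b) data.frame(
    t = day_start_ms(DAY0_IDX + day) + c(1, 2, 3) * 3600000, bssids = b)

  same <- do.call(rbind, lapply(0:2, night, b = "A;B"))
  fp <- learn_home(same)
  expect_identical(fp$bssids, c("A", "B"))
  expect_true(fp$confirmed)

  disjoint <- rbind(night(0, "A"), night(1, "B"), night(2, "C"))
  expect_null(learn_home(disjoint))

  # non-consecutive overlapping nights do not qualify
  gap <- rbind(night(0, "A;B"), night(2, "A;B"), night(4, "A;B"))
  expect_null(learn_home(gap))

  # noise-free simulated subjects: learned fingerprint contains the
  # injected home set for every subject
  streams <- simulate_cohort(sim_cohort_config(n_subjects = 8, weeks = 2,
                                               noise = 0, seed = 19))
  hit <- vapply(streams, function(s) {
    fp <- learn_home(s$wifi, s$tz_offset_min)
    !is.null(fp) && all(attr(s, "truth")$home_bssids %in% fp$bssids)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("GPS metrics match haversine and log-variance oracles", {
  rep3 <- data.frame(t = DAY0 + 1:3, lat = rep(47, 3), lon = rep(8, 3))
  gm <- gps_metrics(rep3)
  expect_equal(gm$total_dist_m, 0)
  expect_equal(gm$max_dist_m, 0)
  expect_equal(gm$loc_var, log(1e-12))  # degenerate day floored

  # two fixes 0.01 degrees apart in latitude: hand haversine
  two <- data.frame(t = DAY0 + 1:2, lat = c(47, 47.01), lon = c(8, 8))
  hand <- 2 * 6371000 * asin(sin(0.01 / 2 * pi / 180))
  gm2 <- gps_metrics(two)
  expect_equal(gm2$total_dist_m, hand, tolerance = 1e-9)
  expect_equal(gm2$max_dist_m, hand, tolerance = 1e-9)

  # population variances 1e-4 + 1e-4 -> loc_var = ln(2e-4)
  four <- data.frame(t = DAY0 + 1:2, lat = 47 + c(-0.01, 0.01),
                     lon = 8 + c(-0.01, 0.01))
  expect_equal(gps_metrics(four)$loc_var, log(2e-4))

  expect_error(gps_metrics(rep3[0, ]), "at least one fix")
})

test_that("location variance grows when spread is scaled up", {
  set.seed(7)
  lat <- 47 + rnorm(20, sd = 0.01); lon <- 8 + rnorm(20, sd = 0.01)
  lv <- function(f) gps_metrics(data.frame(
    t = DAY0 + 1:20,
    lat = mean(lat) + f * (lat - mean(lat)),
    lon = mean(lon) + f * (lon - mean(lon))))$loc_var
  vals <- vapply(c(0.5, 1, 2, 4), lv, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("daily features: empty day, cadence arithmetic, exclusions", {
  s <- make_tiny_stream()
  home <- tiny_home()

  # empty day: all zeros, full missingness mask
  empty <- daily_base_features(s, DAY0_IDX + 5L, home = home)
  expect_true(all(empty[paste0(base_feature_names(), "__mask")] == TRUE))
  expect_true(all(empty[base_feature_names()] == 0))

  d <- daily_base_features(s, DAY0_IDX, home = home)
  # 3 of 4 scans intersect {H1, H2} -> 45 min at home
  expect_equal(d$time_at_home_min, 45)
  expect_equal(d$n_unique_wifi, 5)
  # walking windows: stdev_norm >= 1.5 in 4 of 10 windows -> 8 min
  expect_equal(d$walking_min, 8)
  expect_equal(d$general_activity, mean(s$accel$stdev_norm))
  # phone use: 30 min minus 300 s in-app, plus 15 min untouched
  expect_equal(d$phone_use_min, 30 - 5 + 15)
  # communication counts
  expect_equal(d$calls_in, 1); expect_equal(d$calls_out, 1)
  expect_equal(d$sms_out, 2);  expect_equal(d$sms_in, 0)
  expect_equal(d$sms_unique_contacts, 2)
  expect_equal(d$calls_unique_contacts, 1)
  expect_equal(d$comm_unique_contacts_total, 2)
  expect_equal(d$avg_call_duration_s, 120)
  expect_equal(d$cal_morning, 1); expect_equal(d$cal_afternoon, 1)
  expect_equal(d$cal_evening, 1); expect_equal(d$cal_total, 3)
  expect_equal(d$home_fraction, 45 / 1440)

  # no home fingerprint: time at home flagged missing, not zero
  nh <- daily_base_features(s, DAY0_IDX, home = NULL)
  expect_true(nh$time_at_home_min__mask)
  expect_false(nh$n_unique_wifi__mask)

  # 4 scans at home out of a full 96-scan day -> 60 minutes
  full <- subject_stream("F", DAY0, wifi = data.frame(
    t = DAY0 + (0:95) * 15 * 60000,
    bssids = c(rep("H1", 4), rep("X", 92))))
  fd <- daily_base_features(full, DAY0_IDX, home = home)
  expect_equal(fd$time_at_home_min, 60)
})

test_that("walking + non-walking minutes partition the windowed day", {
  s <- make_tiny_stream()
  d <- daily_base_features(s, DAY0_IDX, home = tiny_home())
  n_win <- sum(floor(s$accel$start / 86400000) == DAY0_IDX)
  non_walking <- sum(s$accel$stdev_norm < 1.5)
  expect_equal(d$walking_min + 2 * non_walking, 2 * n_win)
})

test_that("counting features are additive over disjoint day partitions", {
  s <- make_tiny_stream()
  cut <- DAY0 + 11 * 3600000
  part <- function(lo, hi) {
    keep <- s$comm$t >= lo & s$comm$t < hi
    s2 <- s; s2$comm <- s$comm[keep, ]
    daily_base_features(s2, DAY0_IDX, home = tiny_home())
  }
  whole <- daily_base_features(s, DAY0_IDX, home = tiny_home())
  a <- part(DAY0, cut); b <- part(cut, DAY0 + 86400000)
  for (f in c("sms_in", "sms_out", "calls_in", "calls_out", "sms_total",
              "calls_total"))
    expect_equal(a[[f]] + b[[f]], whole[[f]], label = f)
})

test_that("noise-free simulator days are recovered exactly", {
  p <- sim_profile("REC", severity = 12, noise = 0, phq9_sd = 0, seed = 21)
  s <- simulate_subject(p)
  tr <- attr(s, "truth")$day
  df <- extract_day_features(s)
  rows <- match(tr$day + ms_day(s$enrollment), as.integer(unclass(df$date)))
  expect_equal(df$time_at_home_min[rows], tr$time_at_home_min)
  expect_equal(df$walking_min[rows], tr$walking_min)
  expect_equal(df$calls_total[rows], as.numeric(tr$calls))
  expect_equal(df$sms_total[rows], as.numeric(tr$texts))
})
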