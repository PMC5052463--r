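# Trial-style evaluation statistics: app-use session counting, adherence
# band summaries, biweekly PHQ-9 progression (Wilcoxon signed-rank
# against the synchronized baseline t0) and the Spearman correlation
# between app usage and symptom change.

#' Count qualifying app-use sessions
#'
#' A session counts as one app use iff at least one intervention was
#' executed within it; several executions inside one session still count
#' once.
#'
#' @param sessions data.frame(t, interventions_executed).
#' @return integer count.
#' @export
count_sessions <- function(sessions) {
  sum(sessions$interventions_executed >= 1)
}

#' Per-subject cohort table
#'
#' One row per subject: enrollment, last activity (latest event of any
#' stream), adherence in weeks (last activity minus enrollment),
#' baseline PHQ-9, number of post-baseline PHQ-9 records, qualifying
#' session count, and the full PHQ-9 series as a list column.
#'
#' @param streams list of `subject_stream`s.
#' @return data.frame of class `cohort_table`.
#' @export
cohort_table <- function(streams) {
  rows <- lapply(streams, function(s) {
    all_t <- c(s$accel$start, s$gps$t, s$wifi$t, s$comm$t,
               s$calendar$t_start, s$phoneuse$t_lock, s$sessions$t,
               s$phq9$t)
    last <- if (length(all_t)) max(all_t) else s$enrollment
    q <- s$phq9
    data.frame(
      subject_id = s$subject_id, enrollment = s$enrollment,
      last_activity = last,
      adherence_weeks = (last - s$enrollment) / (7 * MS_PER_DAY),
      baseline_phq9 = if (nrow(q)) q$score[1] else NA_integer_,
      n_post_baseline = max(0L, nrow(q) - 1L),
      sessions_total = count_sessions(s$sessions))
  })
  out <- do.call(rbind, rows)
  out$phq9 <- lapply(streams, `[[`, "phq9")
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Adherence band summary
#'
#' Fractions of the cohort that (a) left within the first 2 weeks,
#' (b) left during weeks 2-4, (c) adhered 4 weeks or longer while
#' providing at least 2 post-baseline PHQ-9 measures, and (d) anything
#' else (long adherence but too few questionnaires).  Percentages are
#' rounded to one decimal.
#'
#' @param cohort a [cohort_table()] or any data.frame with
#'   `adherence_weeks` and `n_post_baseline` columns.
#' @return data.frame(band, n, pct).
#' @export
adherence_summary <- function(cohort) {
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  w <- cohort$adherence_weeks
  q <- cohort$n_post_baseline
  band <- ifelse(w < 2, "under_2wk",
                 ifelse(w < 4, "wk2_to_4",
                        ifelse(q >= 2, "wk4_plus", "other")))
  lv <- c("under_2wk", "wk2_to_4", "wk4_plus", "other")
  n <- as.integer(table(factor(band, levels = lv)))
  data.frame(band = lv, n = n,
             pct = round(100 * n / nrow(cohort), 1))
}

#' Wilcoxon signed-rank test
#'
#' Paired test of `x` against `y` (or of `x` against `mu` when `y` is
#' missing).  Zero differences are dropped (the original convention);
#' the statistic is the sum of positive signed ranks.  The p-value is
#' exact (from the signed-rank null distribution) when there are no ties
#' among the absolute differences and at most 25 remain, otherwise a
#' normal approximation with tie correction and continuity correction is
#' used.  The reported `z` is always the (continuity-corrected) normal
#' deviate, signed so that `x > y` pushes it positive.
#'
#' @param x,y paired numeric vectors (same length), or `x` alone.
#' @param mu null location when `y` is missing.
#' @return a `test_result` list: `statistic` (z), `W`, `p`, `n`
#'   (non-zero pairs), `method`, `exact`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, mu = 0) {
  d <- if (is.null(y)) x - mu else {
    stopifnot(length(x) == length(y))
    x - y
  }
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(structure(list(statistic = 0, W = 0, p = 1, n = 0L,
                          method = "wilcoxon_signed_rank", exact = FALSE,
                          degenerate = TRUE), class = "test_result"))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu_w <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (sig2 > 0)
    (W - mu_w - 0.5 * sign(W - mu_w)) / sqrt(sig2) else 0
  no_ties <- !any(duplicated(abs(d)))
  if (no_ties && n <= 25) {
    p <- min(1, 2 * min(stats::psignrank(W, n),
                        1 - stats::psignrank(W - 1, n)))
    exact <- TRUE
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  structure(list(statistic = z, W = W, p = p, n = as.integer(n),
                 method = "wilcoxon_signed_rank", exact = exact,
                 degenerate = FALSE), class = "test_result")
}

#' Spearman rank correlation test
#'
#' Rho is the Pearson correlation of the (midrank-tied) ranks; the
#' two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length.
#' @return a `test_result` list: `statistic` (rho), `p`, `n`, `method`,
#'   `degenerate` (TRUE when either variable is constant, rho
#'   undefined).
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(list(statistic = NA_real_, p = NA_real_,
                          n = as.integer(n), method = "spearman",
                          degenerate = TRUE), class = "test_result"))
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  structure(list(statistic = rho, p = p, n = as.integer(n),
                 method = "spearman", degenerate = FALSE),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic=%.4g, p=%.4g, n=%d%s\n",
              x$method, x$statistic, x$p, x$n,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Biweekly PHQ-9 progression tests against baseline
#'
#' For the subgroup with a clinically relevant baseline
#' (PHQ-9 >= `baseline_min`), adherence of at least
#' `min_adherence_weeks` and at least `min_post` post-baseline
#' questionnaires, runs a Wilcoxon signed-rank test of the synchronized
#' baseline t0 against every later biweekly horizon tn (subjects enter a
#' horizon if they reached it).  Differences are taken t0 - tn, so a
#' symptom drop gives a positive z.  Medians and interquartile ranges of
#' both time points are reported per horizon, together with a
#' Kolmogorov-Smirnov normality check of the paired differences (the
#' rationale for using a rank test in the first place).
#'
#' @param cohort a [cohort_table()].
#' @param baseline_min clinical inclusion threshold at t0.
#' @param min_adherence_weeks minimal adherence for inclusion.
#' @param min_post minimal post-baseline PHQ-9 count for inclusion.
#' @param min_n minimal eligible subjects per tested horizon.
#' @return data.frame: one row per horizon (`weeks`), with `n`, `z`,
#'   `p`, `exact`, medians/IQRs at t0 and tn, and `ks_p`.
#' @export
phq9_progression_test <- function(cohort, baseline_min = 11,
                                  min_adherence_weeks = 4, min_post = 2,
                                  min_n = 5) {
  el <- cohort$baseline_phq9 >= baseline_min &
    cohort$adherence_weeks >= min_adherence_weeks &
    cohort$n_post_baseline >= min_post
  series <- cohort$phq9[el]
  if (length(series) == 0) stop("no eligible subjects", call. = FALSE)
  max_h <- max(vapply(series, nrow, integer(1))) - 1L
  rows <- list()
  for (h in seq_len(max_h)) {
    t0 <- vapply(series, function(q) q$score[1], numeric(1))
    tn <- vapply(series, function(q)
      if (nrow(q) > h) q$score[h + 1] else NA_real_, numeric(1))
    keep <- !is.na(tn)
    if (sum(keep) < min_n) next
    t0k <- t0[keep]; tnk <- tn[keep]
    wt <- wilcoxon_signed_rank(t0k, tnk)
    d <- t0k - tnk
    ks_p <- if (stats::sd(d) > 0)
      suppressWarnings(stats::ks.test(d, "pnorm", mean(d),
                                      stats::sd(d))$p.value)
    else NA_real_
    q0 <- stats::quantile(t0k, c(0.25, 0.5, 0.75))
    qn <- stats::quantile(tnk, c(0.25, 0.5, 0.75))
    rows[[h]] <- data.frame(
      weeks = 2L * h, n = sum(keep), z = wt$statistic, p = wt$p,
      exact = wt$exact, degenerate = wt$degenerate,
      median_tn = qn[2], iqr_lo_tn = qn[1], iqr_hi_tn = qn[3],
      median_t0 = q0[2], iqr_lo_t0 = q0[1], iqr_hi_t0 = q0[3],
      ks_p = ks_p, row.names = NULL)
  }
  if (length(rows) == 0) stop("no horizon with at least ", min_n,
                              " eligible subjects", call. = FALSE)
  do.call(rbind, rows)
}

#' Usage-symptom correlation
#'
#' Spearman correlation between the total number of qualifying app
#' sessions and the change in PHQ-9 between the synchronized baseline t0
#' and each subject's last measure t_end, over the same clinical,
#' adherent subgroup as [phq9_progression_test()].
#'
#' @inheritParams phq9_progression_test
#' @return a `test_result` from [spearman_test()].
#' @export
usage_symptom_correlation <- function(cohort, baseline_min = 11,
                                      min_adherence_weeks = 4,
                                      min_post = 2) {
  el <- cohort$baseline_phq9 >= baseline_min &
    cohort$adherence_weeks >= min_adherence_weeks &
    cohort$n_post_baseline >= min_post
  if (sum(el) < 5) stop("need at least 5 eligible subjects", call. = FALSE)
  usage <- cohort$sessions_total[el]
  delta <- vapply(cohort$phq9[el], function(q)
    q$score[nrow(q)] - q$score[1], numeric(1))
  spearman_test(usage, delta)
}
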