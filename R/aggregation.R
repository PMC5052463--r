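# Aggregation of per-day features into the 120-dimensional descriptor of
# the 14 days preceding each biweekly PHQ-9 self report: for each of the
# 24 base features, the mean, sum, variance (population), minimum and
# maximum of the daily values.

AGG_STATS <- c("mean", "sum", "variance", "min", "max")

#' Canonical 120-feature name list
#'
#' `<base>__<stat>` for the 24 base features of [base_feature_names()]
#' crossed with the five statistics (mean, sum, variance, min, max), in
#' that order — base feature major, statistic minor.  The order is fixed
#' and regression-tested.
#'
#' @return character vector of length 120.
#' @export
feature_vector_names <- function() {
  as.vector(t(outer(base_feature_names(), AGG_STATS, paste, sep = "__")))
}

#' Build one 120-dimensional feature vector
#'
#' Takes the 14 consecutive day rows preceding a PHQ-9 record and returns
#' the descriptive statistics of each base feature over its unmasked
#' days.  A base feature observed on fewer than `min_valid_days` days has
#' all five of its statistics set to `NA` (masked); if more than
#' `max_masked_features` base features are masked the whole vector is
#' dropped (`NULL`), mirroring a subject too poorly sensed to score.
#'
#' @param day_features data.frame of exactly 14 consecutive day rows as
#'   produced by [extract_day_features()] (the 14 calendar days before
#'   the PHQ-9 prompt, in order).
#' @param phq9 one-row data.frame(t, score) — the paired PHQ-9 record.
#' @param subject_id subject identifier carried into the result.
#' @param min_valid_days minimum unmasked days per base feature.
#' @param max_masked_features maximum number of masked base features
#'   before the vector is dropped.
#' @param cutoff clinical threshold defining the positive label.
#' @return a `feature_vector` (list with `subject_id`, `phq9_time`,
#'   `score`, `label`, `values` — named numeric of length 120) or `NULL`.
#' @export
feature_vector <- function(day_features, phq9, subject_id = "?",
                           min_valid_days = 7, max_masked_features = 4,
                           cutoff = 11) {
  if (nrow(day_features) != 14)
    stop("need exactly the 14 days preceding the PHQ-9 record",
         call. = FALSE)
  if (is.unsorted(day_features$date, strictly = TRUE))
    stop("day rows must be consecutive and ordered", call. = FALSE)
  base <- base_feature_names()
  vals <- stats::setNames(rep(NA_real_, 120), feature_vector_names())
  masked <- 0L
  for (b in base) {
    x <- day_features[[b]]
    mask <- day_features[[paste0(b, "__mask")]]
    x <- x[!mask]
    if (length(x) < min_valid_days) { masked <- masked + 1L; next }
    vals[paste(b, AGG_STATS, sep = "__")] <-
      c(mean(x), sum(x), pop_var(x), min(x), max(x))
  }
  if (masked > max_masked_features) return(NULL)
  structure(list(subject_id = subject_id, phq9_time = phq9$t[1],
                 score = phq9$score[1],
                 label = as.integer(phq9$score[1] >= cutoff),
                 values = vals),
            class = "feature_vector")
}

#' All feature vectors for one subject
#'
#' Pairs every PHQ-9 record preceded by a full 14-day sensing window with
#' its descriptor.  The baseline record (no 14 prior days) yields no
#' vector.
#'
#' @param stream a validated `subject_stream`.
#' @param day_features optional precomputed [extract_day_features()]
#'   table.
#' @param ... passed to [feature_vector()].
#' @return list of `feature_vector` objects (possibly empty).
#' @export
subject_feature_vectors <- function(stream,
                                    day_features = extract_day_features(stream),
                                    ...) {
  tz <- stream$tz_offset_min
  day_idx <- as.integer(unclass(day_features$date))
  out <- list()
  for (i in seq_len(nrow(stream$phq9))) {
    rec <- stream$phq9[i, ]
    d <- ms_day(rec$t, tz)
    want <- (d - 14):(d - 1)
    rows <- match(want, day_idx)
    if (anyNA(rows)) next
    fv <- feature_vector(day_features[rows, ], rec,
                         subject_id = stream$subject_id, ...)
    if (!is.null(fv)) out[[length(out) + 1L]] <- fv
  }
  out
}

#' Assemble a labeled dataset from many subjects
#'
#' @param streams list of `subject_stream`s (e.g. [simulate_cohort()]).
#' @param ... passed to [feature_vector()].
#' @return data.frame: `subject_id`, `phq9_time`, `score`, `label`, then
#'   the 120 feature columns of [feature_vector_names()].
#' @export
build_dataset <- function(streams, ...) {
  vecs <- unlist(lapply(streams, subject_feature_vectors, ...),
                 recursive = FALSE)
  if (length(vecs) == 0) stop("no feature vectors could be built",
                              call. = FALSE)
  head_df <- data.frame(
    subject_id = vapply(vecs, `[[`, character(1), "subject_id"),
    phq9_time = vapply(vecs, `[[`, numeric(1), "phq9_time"),
    score = vapply(vecs, `[[`, numeric(1), "score"),
    label = vapply(vecs, `[[`, integer(1), "label"))
  X <- do.call(rbind, lapply(vecs, `[[`, "values"))
  cbind(head_df, as.data.frame(X))
}
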