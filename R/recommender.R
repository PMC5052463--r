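# Context-sensitive intervention recommender.  Baskets of CBT
# interventions are scored against the last 24 hours of behavior as a
# weighted sum of range-scaled feature values; interventions inside a
# presented basket are ranked by a preference score built from past star
# ratings, the early-cancellation rate and a small chance bonus, subject
# to eligibility rules (home/away, time slot) and post-execution block
# timers.  Phase 1 uses population assumption ranges; after two weeks of
# observation, ranges are personalized to the subject's own week
# (mu +/- 2 sd).

#' Linear range scaling
#'
#' Fraction of the `[x_min, x_max]` range reached by `x`, clamped to
#' `[0, 1]`.
#'
#' @param x value(s) of a context feature over the last 24 hours.
#' @param x_min,x_max range bounds, `x_max > x_min`.
#' @return numeric in `[0, 1]`.
#' @export
scale_to_range <- function(x, x_min, x_max) {
  if (any(x_max <= x_min)) stop("x_max must exceed x_min", call. = FALSE)
  pmin(1, pmax(0, (x - x_min) / (x_max - x_min)))
}

#' Population assumption ranges (phase 1)
#'
#' Daily-magnitude ranges assumed for the general depressed population:
#' time at home spans 7..14 h/day, total calls 0..6/day, walking
#' 30..300 min/day; the remaining recommender features (texts, calendar
#' events, average call duration, phone use) carry package-chosen
#' defaults in the same spirit, since only directions are established
#' for them.
#'
#' @return named list of `feature_range` lists
#'   (`x_min`, `x_max`, `source`).
#' @export
population_ranges <- function() {
  mk <- function(lo, hi) list(x_min = lo, x_max = hi, source = "population")
  list(
    time_at_home_min    = mk(7 * 60, 14 * 60),
    calls_total         = mk(0, 6),
    walking_min         = mk(30, 300),
    sms_total           = mk(0, 10),
    cal_total           = mk(0, 4),
    avg_call_duration_s = mk(0, 600),
    phone_use_min       = mk(60, 300)
  )
}

#' Personalized feature ranges (phase 2)
#'
#' After two weeks of enrollment the population assumptions are replaced
#' by the subject's own behavior: per feature, the mean of the last
#' week's daily values plus/minus twice their standard deviation.
#' Degenerate (zero-variance) ranges are widened symmetrically to
#' `min_width`; lower bounds of non-negative features are clipped at 0.
#'
#' @param day_features data.frame of the subject's last-week day rows
#'   ([extract_day_features()] layout); masked days are ignored per
#'   feature.
#' @param features which features to build ranges for.
#' @param min_width minimum range width after widening.
#' @param min_days minimum valid days per feature (else that feature is
#'   skipped).
#' @return named list of `feature_range` lists with
#'   `source = "personalized"`.
#' @export
personalize_ranges <- function(day_features,
                               features = names(population_ranges()),
                               min_width = 1, min_days = 2) {
  out <- list()
  for (f in features) {
    x <- day_features[[f]]
    if (is.null(x)) next
    mask <- day_features[[paste0(f, "__mask")]]
    if (!is.null(mask)) x <- x[!mask]
    if (length(x) < min_days) next
    mu <- mean(x); sdv <- stats::sd(x)
    lo <- mu - 2 * sdv; hi <- mu + 2 * sdv
    if (hi - lo < min_width) {  # widen degenerate range
      lo <- mu - min_width / 2; hi <- mu + min_width / 2
    }
    lo <- max(0, lo)
    if (hi <= lo) hi <- lo + min_width
    out[[f]] <- list(x_min = lo, x_max = hi, source = "personalized")
  }
  out
}

#' Score one basket against the current context
#'
#' Weighted sum of range-scaled context features:
#' `sum_n w_n * scale_to_range(x_n, x_n_min, x_n_max)`.
#'
#' @param basket a basket from [default_catalog()]: list with `id`,
#'   `domain`, `weights` (named numeric), `interventions`.
#' @param ctx a [context_24h()].
#' @param ranges named list of feature ranges ([population_ranges()] or
#'   [personalize_ranges()]).
#' @return scalar score.
#' @export
basket_score <- function(basket, ctx, ranges = population_ranges()) {
  w <- basket$weights
  if (length(w) == 0) return(0)
  s <- 0
  for (f in names(w)) {
    r <- ranges[[f]]
    if (is.null(r))
      stop("no range defined for feature '", f, "'", call. = FALSE)
    x <- ctx$features[[f]]
    if (is.null(x) || is.na(x))
      stop("context lacks feature '", f, "'", call. = FALSE)
    s <- s + w[[f]] * scale_to_range(x, r$x_min, r$x_max)
  }
  s
}

#' Preference score of one intervention
#'
#' `0.75 * mean(past ratings)/5 - 0.25 * cancellation rate`, plus a
#' `+0.5` chance bonus when the supplied uniform draw is at most 0.05.
#' The cancellation rate is cancellations over total attempts
#' (executions + cancellations).  Unrated interventions score with a
#' neutral prior rating; never-attempted ones have rate 0.
#'
#' @param state an intervention state (list with `ratings`,
#'   `cancellations`, `executions`).
#' @param rng_draw uniform draw in `[0, 1)`, injectable for testing.
#' @param prior_rating rating assumed before any feedback exists.
#' @return scalar score.
#' @export
intervention_score <- function(state, rng_draw, prior_rating = 3) {
  ratings <- state$ratings
  mean_rating <- if (length(ratings)) mean(ratings) else prior_rating
  attempts <- state$executions + state$cancellations
  cancel_rate <- if (attempts > 0) state$cancellations / attempts else 0
  0.75 * mean_rating / 5 - 0.25 * cancel_rate +
    if (rng_draw <= 0.05) 0.5 else 0
}

#' Post-execution block time
#'
#' Hours an intervention is blocked after execution, decreasing in the
#' subject's star rating: `36 * (6 - rating)` (36 h for 5 stars up to
#' 180 h for 1 star).
#'
#' @param last_rating integer star rating in 1..5.
#' @return hours.
#' @export
block_time <- function(last_rating) {
  if (any(!last_rating %in% 1:5))
    stop("rating must be an integer in 1..5", call. = FALSE)
  36 * (6 - last_rating)
}

#' Record an execution + rating, updating the block timer
#'
#' @param state an intervention state.
#' @param rating star rating in 1..5.
#' @param now epoch ms of the execution.
#' @return updated state with `blocked_until` advanced by
#'   [block_time()] hours.
#' @export
record_execution <- function(state, rating, now) {
  state$ratings <- c(state$ratings, as.integer(rating))
  state$executions <- state$executions + 1L
  state$blocked_until <- now + block_time(rating) * 3600000
  state
}

#' Record an early cancellation
#'
#' @param state an intervention state.
#' @return updated state.
#' @export
record_cancellation <- function(state) {
  state$cancellations <- state$cancellations + 1L
  state
}

new_intervention <- function(id, basket_id, type,
                             rules = list(location = NULL, slots = NULL),
                             duration_min = 10) {
  list(id = id, basket_id = basket_id, type = type, rules = rules,
       duration_min = duration_min, ratings = integer(0),
       cancellations = 0L, executions = 0L, blocked_until = -Inf)
}

#' Default basket and intervention catalog
#'
#' Four baskets, one per intervention domain (physical, social,
#' mindfulness, relaxation), each holding metadata stubs for a handful
#' of interventions tagged with one of the eight interactive types
#' (activity tracker, quiz, checkbox, button, mirror, audio, multitext,
#' countdown) and optional eligibility rules.  The feature weights are a
#' documented package default standing in for the expert-set values
#' (e.g. the physical basket weighs walking and phone use so that a
#' sedentary, home-bound day raises its score); all weights are plain
#' data and fully overridable.
#'
#' @return list of baskets.
#' @export
default_catalog <- function() {
  list(
    list(id = "physical", domain = "physical",
         weights = c(walking_min = -1, time_at_home_min = 0.5,
                     phone_use_min = 0.25),
         interventions = list(
           new_intervention("walk_10min", "physical", "activity_tracker",
                            rules = list(location = NULL, slots = NULL)),
           new_intervention("morning_exercise", "physical", "button",
                            rules = list(location = "home",
                                         slots = "morning")),
           new_intervention("chair_hold", "physical", "countdown"),
           new_intervention("stairs_not_lift", "physical", "checkbox"))),
    list(id = "social", domain = "social",
         weights = c(calls_total = -0.75, sms_total = -0.5,
                     time_at_home_min = 0.5),
         interventions = list(
           new_intervention("call_friend", "social", "checkbox"),
           new_intervention("movies_popcorn", "social", "checkbox",
                            rules = list(slots = c("afternoon",
                                                   "evening"))),
           new_intervention("kaffeeklatsch", "social", "checkbox"),
           new_intervention("smile_mirror", "social", "mirror"))),
    list(id = "mindfulness", domain = "mindfulness",
         weights = c(cal_total = 0.5, phone_use_min = 0.5),
         interventions = list(
           new_intervention("muse_chair", "mindfulness", "multitext"),
           new_intervention("new_perspective", "mindfulness", "quiz"),
           new_intervention("praise_yourself", "mindfulness", "checkbox"),
           new_intervention("awareness_intro", "mindfulness",
                            "multitext"))),
    list(id = "relaxation", domain = "relaxation",
         weights = c(phone_use_min = 0.5, cal_total = 0.5,
                     walking_min = -0.25),
         interventions = list(
           new_intervention("breathing_audio", "relaxation", "audio"),
           new_intervention("lie_down_relax", "relaxation", "audio",
                            rules = list(location = "home",
                                         slots = c("morning",
                                                   "evening"))),
           new_intervention("muscle_release", "relaxation", "countdown"),
           new_intervention("body_scan", "relaxation", "multitext"))))
}

#' Last-24-hour context
#'
#' @param features named numeric of feature magnitudes over the trailing
#'   24 hours (same units as the day features).
#' @param at_home logical: is the subject currently at home?
#' @param slot current day slot ("morning", "afternoon" or "evening").
#' @param now epoch ms.
#' @return a `context_24h` list.
#' @export
context_24h <- function(features, at_home, slot, now) {
  stopifnot(slot %in% c("morning", "afternoon", "evening"),
            is.logical(at_home))
  structure(list(features = as.list(features), at_home = at_home,
                 slot = slot, now = now),
            class = "context_24h")
}

# eligibility: location and slot rules must all hold
intervention_eligible <- function(iv, ctx) {
  r <- iv$rules
  if (!is.null(r$location)) {
    if (r$location == "home" && !ctx$at_home) return(FALSE)
    if (r$location == "away" && ctx$at_home) return(FALSE)
  }
  if (!is.null(r$slots) && !(ctx$slot %in% r$slots)) return(FALSE)
  TRUE
}

#' Rank baskets and interventions for the current context
#'
#' Scores every basket with [basket_score()], orders baskets by
#' decreasing score (ties broken by basket id), and inside each basket
#' ranks the eligible, unblocked interventions by [intervention_score()]
#' (fed one uniform draw per intervention from `rng_draws`, or from the
#' session RNG), returning the top `top_k`.  Baskets whose top set was
#' fully completed or neglected this epoch are dropped from display
#' until the next 6-hour evaluation; baskets with every intervention
#' blocked or ineligible are flagged empty.  Each basket also gets a
#' display radius increasing monotonically in its score.
#'
#' @param ctx a [context_24h()].
#' @param baskets catalog, see [default_catalog()].
#' @param ranges feature ranges (population or personalized).
#' @param top_k interventions shown per basket.
#' @param exhausted_baskets character ids to hide this epoch.
#' @param rng_draws optional named/unnamed numeric vector of uniform
#'   draws, one per catalog intervention in catalog order (injectable
#'   for deterministic tests).
#' @param prior_rating see [intervention_score()].
#' @return a `recommendation`: list with `epoch` (6-hour evaluation
#'   epoch index of `ctx$now`) and `baskets`, each holding `id`,
#'   `score`, `radius`, `empty` and the ranked `top` interventions
#'   (id + score).
#' @export
recommend <- function(ctx, baskets = default_catalog(),
                      ranges = population_ranges(), top_k = 3,
                      exhausted_baskets = character(0), rng_draws = NULL,
                      prior_rating = 3) {
  if (length(baskets) == 0) stop("need at least one basket", call. = FALSE)
  n_iv <- sum(vapply(baskets, function(b) length(b$interventions),
                     integer(1)))
  if (is.null(rng_draws)) rng_draws <- stats::runif(n_iv)
  if (length(rng_draws) != n_iv)
    stop("need one rng draw per catalog intervention", call. = FALSE)

  scores <- vapply(baskets, basket_score, numeric(1), ctx = ctx,
                   ranges = ranges)
  ids <- vapply(baskets, `[[`, character(1), "id")
  ord <- order(-scores, ids)

  # display radius: affine in score, monotone, bounded away from zero
  lo <- min(scores); hi <- max(scores)
  radius <- if (hi > lo) 0.5 + 0.5 * (scores - lo) / (hi - lo) else
    rep(1, length(scores))

  # draw offsets follow catalog order, not rank order
  n_per <- vapply(baskets, function(b) length(b$interventions), integer(1))
  offsets <- c(0L, cumsum(n_per))
  out <- list()
  for (k in ord) {
    b <- baskets[[k]]
    draws_b <- rng_draws[offsets[k] + seq_len(n_per[k])]
    if (b$id %in% exhausted_baskets) next
    ok <- vapply(b$interventions, function(iv)
      intervention_eligible(iv, ctx) && iv$blocked_until < ctx$now,
      logical(1))
    entry <- list(id = b$id, domain = b$domain, score = scores[k],
                  radius = radius[k], empty = !any(ok), top = list())
    if (any(ok)) {
      ivs <- b$interventions[ok]
      sc <- vapply(seq_along(ivs), function(j)
        intervention_score(ivs[[j]], draws_b[ok][j],
                           prior_rating = prior_rating), numeric(1))
      iv_ids <- vapply(ivs, `[[`, character(1), "id")
      o <- order(-sc, iv_ids)
      take <- utils::head(o, top_k)
      entry$top <- Map(function(id, s) list(id = id, score = s),
                       iv_ids[take], sc[take])
    }
    out[[length(out) + 1L]] <- entry
  }
  structure(list(epoch = evaluation_epoch(ctx$now), baskets = out),
            class = "recommendation")
}

#' 6-hour evaluation epoch of a timestamp
#'
#' Context re-evaluation happens every 6 hours with boundaries at local
#' 00/06/12/18; the epoch index is the count of 6-hour blocks since the
#' Unix epoch.
#'
#' @param t epoch ms.
#' @param tz_offset_min subject clock offset.
#' @return integer epoch index.
#' @export
evaluation_epoch <- function(t, tz_offset_min = 0) {
  as.integer(floor((t + tz_offset_min * MS_PER_MIN) / (6 * 3600000)))
}
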