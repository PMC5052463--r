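test_that("range scaling is linear, clamped and validated", {
  expect_equal(scale_to_range(30, 30, 300), 0)
  expect_equal(scale_to_range(300, 30, 300), 1)
  expect_equal(scale_to_range(165, 30, 300), 0.5)
  expect_equal(scale_to_range(-10, 0, 6), 0)     # clamp below
  expect_equal(scale_to_range(9, 0, 6), 1)       # clamp above
  expect_error(scale_to_range(1, 5, 5), "exceed")
})

test_that("basket scoring evaluates the weighted scaled sum", {
  ranges <- list(f1 = list(x_min = 0, x_max = 10, source = "population"),
                 f2 = list(x_min = 0, x_max = 4, source = "population"))
  ctx <- context_24h(c(f1 = 5, f2 = 4), at_home = TRUE, slot = "morning",
                     now = DAY0)
  b0 <- list(id = "b0", domain = "social", weights = numeric(0),
             interventions = list())
  expect_equal(basket_score(b0, ctx, ranges), 0)

  b1 <- list(id = "b1", domain = "social", weights = c(f2 = 1),
             interventions = list())
  expect_equal(basket_score(b1, ctx, ranges), 1)  # x at range max

  # w = (2, -1) with scaled values (0.5, 1.0): 2*0.5 - 1*1 = 0
  b2 <- list(id = "b2", domain = "social", weights = c(f1 = 2, f2 = -1),
             interventions = list())
  expect_equal(basket_score(b2, ctx, ranges), 0)

  expect_error(basket_score(list(id = "x", weights = c(nope = 1)),
                            ctx, ranges), "no range.*nope")
})

test_that("basket score is linear in each weight", {
  ranges <- population_ranges()
  ctx <- context_24h(c(walking_min = 100, time_at_home_min = 500,
                       phone_use_min = 120), TRUE, "morning", DAY0)
  mk <- function(w) list(id = "p", domain = "physical", weights = w,
                         interventions = list())
  base <- c(walking_min = -1, time_at_home_min = 0.5, phone_use_min = 0.2)
  s0 <- basket_score(mk(base), ctx, ranges)
  for (f in names(base)) {
    w2 <- base; w2[f] <- w2[f] + 1
    delta <- basket_score(mk(w2), ctx, ranges) - s0
    r <- ranges[[f]]
    expect_equal(delta, scale_to_range(ctx$features[[f]], r$x_min,
                                       r$x_max),
                 label = f)
  }
})

test_that("personalized ranges are mu +/- 2 sd with degenerate widening", {
  mk_days <- function(x, f = "walking_min") {
    df <- data.frame(rep(0, length(x)))
    names(df) <- "dummy"
    df[[f]] <- x
    df[[paste0(f, "__mask")]] <- FALSE
    df
  }
  # constant 10 with min width 1 -> widened to [9.5, 10.5]
  r <- personalize_ranges(mk_days(rep(10, 7)), features = "walking_min",
                          min_width = 1)
  expect_equal(r$walking_min$x_min, 9.5)
  expect_equal(r$walking_min$x_max, 10.5)
  expect_identical(r$walking_min$source, "personalized")

  # mean 8, sd 2 -> [4, 12]
  r2 <- personalize_ranges(mk_days(c(6, 8, 10)), features = "walking_min")
  expect_equal(r2$walking_min$x_min, 4)
  expect_equal(r2$walking_min$x_max, 12)

  # simulated week matches the brute-force formula per feature
  s <- simulate_subject(sim_profile("P2", severity = 14, seed = 4))
  df <- utils::head(extract_day_features(s), 7)
  rr <- personalize_ranges(df)
  for (f in names(rr)) {
    x <- df[[f]][!df[[paste0(f, "__mask")]]]
    expect_equal(rr[[f]]$x_min, max(0, mean(x) - 2 * sd(x)), label = f)
    expect_equal(rr[[f]]$x_max, mean(x) + 2 * sd(x), label = f)
  }

  # count features are clipped below at zero
  r3 <- personalize_ranges(mk_days(c(0, 1, 0, 2, 1), "calls_total"),
                           features = "calls_total")
  expect_gte(r3$calls_total$x_min, 0)
})

test_that("phase-2 ranges reproduce phase-1 scores when behavior matches
           the population anchors", {
  pop <- population_ranges()
  days <- data.frame(dummy = rep(0, 3))
  for (f in names(pop)) {
    mid <- (pop[[f]]$x_min + pop[[f]]$x_max) / 2
    s <- (pop[[f]]$x_max - pop[[f]]$x_min) / 4  # mu +/- 2s hits bounds
    days[[f]] <- c(mid - s, mid, mid + s)
    days[[paste0(f, "__mask")]] <- FALSE
  }
  pers <- personalize_ranges(days)
  ctx <- context_24h(c(walking_min = 120, time_at_home_min = 600,
                       calls_total = 3, sms_total = 4, cal_total = 2,
                       avg_call_duration_s = 100, phone_use_min = 200),
                     TRUE, "evening", DAY0)
  for (b in default_catalog())
    expect_equal(basket_score(b, ctx, pers), basket_score(b, ctx, pop),
                 label = b$id)
})

test_that("intervention scoring follows the published closed form", {
  st <- function(ratings, canc = 0L, exec = length(ratings))
    list(ratings = ratings, cancellations = canc, executions = exec)
  # 5 stars, never cancelled, no bonus -> 0.75
  expect_equal(intervention_score(st(5L), 0.5), 0.75)
  # 5 stars but always cancelled -> 0.75 - 0.25 = 0.5
  expect_equal(intervention_score(list(ratings = 5L, cancellations = 1L,
                                       executions = 0L), 0.5), 0.5)
  # mean rating 2.5, cancellation rate 0.5, bonus fires -> 0.75
  expect_equal(intervention_score(list(ratings = c(2L, 3L),
                                       cancellations = 1L,
                                       executions = 1L), 0.01), 0.75)
  # unrated: neutral prior 3 stars, no attempts -> 0.45
  expect_equal(intervention_score(st(integer(0), 0L, 0L), 0.5), 0.45)
  # bonus boundary is inclusive at 0.05
  expect_equal(intervention_score(st(5L), 0.05) -
                 intervention_score(st(5L), 0.051), 0.5)
})

test_that("intervention score stays inside its analytic range", {
  set.seed(11)
  for (i in 1:200) {
    nr <- sample(0:6, 1)
    st <- list(ratings = sample(1:5, nr, replace = TRUE),
               cancellations = sample(0:3, 1),
               executions = nr)
    draw <- runif(1)
    sc <- intervention_score(st, draw)
    bonus <- if (draw <= 0.05) 0.5 else 0
    expect_gte(sc, 0.75 * 1 / 5 - 0.25 + bonus - 1e-12)
    expect_lte(sc, 0.75 + bonus + 1e-12)
  }
})

test_that("chance bonus fires at the nominal 5% rate", {
  set.seed(2024)
  draws <- runif(4000)
  st <- list(ratings = 3L, cancellations = 0L, executions = 1L)
  fired <- vapply(draws, function(d)
    intervention_score(st, d) > 0.6, logical(1))
  bt <- stats::binom.test(sum(fired), length(draws), p = 0.05)
  expect_gt(bt$p.value, 0.001)
})

test_that("block time is 36 * (6 - rating) hours, decreasing in rating", {
  expect_equal(block_time(5), 36)
  expect_equal(block_time(1), 180)
  expect_true(all(diff(block_time(1:5)) < 0))
  expect_error(block_time(0), "1\\.\\.5")
  expect_error(block_time(6), "1\\.\\.5")

  st <- list(ratings = integer(0), cancellations = 0L, executions = 0L,
             blocked_until = -Inf)
  st2 <- record_execution(st, 4, DAY0)
  expect_equal(st2$blocked_until, DAY0 + 72 * 3600000)
  expect_identical(st2$executions, 1L)
})

test_that("recommendation ranks, filters and blocks correctly", {
  cat <- default_catalog()
  n_iv <- sum(vapply(cat, function(b) length(b$interventions), integer(1)))
  no_bonus <- rep(0.5, n_iv)

  # a context away from home in the afternoon excludes the lie-down
  # relaxation exercise (home + morning/evening rule)
  ctx_away <- context_24h(
    c(walking_min = 20, time_at_home_min = 300, phone_use_min = 200,
      calls_total = 1, sms_total = 1, cal_total = 1,
      avg_call_duration_s = 60), at_home = FALSE, slot = "afternoon",
    now = DAY0)
  rec <- recommend(ctx_away, cat, rng_draws = no_bonus)
  relax <- rec$baskets[[which(vapply(rec$baskets, `[[`, character(1),
                                     "id") == "relaxation")]]
  shown <- vapply(relax$top, `[[`, character(1), "id")
  expect_false("lie_down_relax" %in% shown)
  expect_false("morning_exercise" %in% unlist(lapply(rec$baskets,
    function(b) vapply(b$top, `[[`, character(1), "id"))))

  # at home in the evening it is eligible again
  ctx_home <- context_24h(ctx_away$features, TRUE, "evening", DAY0)
  rec2 <- recommend(ctx_home, cat, rng_draws = no_bonus)
  relax2 <- rec2$baskets[[which(vapply(rec2$baskets, `[[`, character(1),
                                       "id") == "relaxation")]]
  expect_true("lie_down_relax" %in% vapply(relax2$top, `[[`,
                                           character(1), "id"))

  # deterministic given fixed draws
  expect_identical(recommend(ctx_home, cat, rng_draws = no_bonus),
                   recommend(ctx_home, cat, rng_draws = no_bonus))

  # display radius is monotone in basket score
  sc <- vapply(rec2$baskets, `[[`, numeric(1), "score")
  rad <- vapply(rec2$baskets, `[[`, numeric(1), "radius")
  expect_true(all(diff(sc) <= 0))
  expect_true(all(diff(rad) <= 1e-12))
})

test_that("top-3 selection matches a brute-force sort oracle", {
  ivs <- lapply(1:5, function(i) {
    iv <- list(id = paste0("iv", i), basket_id = "b", type = "checkbox",
               rules = list(), duration_min = 5,
               ratings = as.integer(i), cancellations = 0L,
               executions = 1L, blocked_until = -Inf)
    iv
  })
  b <- list(id = "b", domain = "social", weights = c(calls_total = -1),
            interventions = ivs)
  ctx <- context_24h(c(calls_total = 2), TRUE, "morning", DAY0)
  draws <- rep(0.5, 5)
  rec <- recommend(ctx, list(b), rng_draws = draws)
  got <- vapply(rec$baskets[[1]]$top, `[[`, character(1), "id")

  oracle_scores <- vapply(ivs, intervention_score, numeric(1),
                          rng_draw = 0.5)
  oracle <- vapply(ivs, `[[`, character(1), "id")[
    order(-oracle_scores)][1:3]
  expect_identical(unname(got), oracle)
  expect_length(rec$baskets[[1]]$top, 3)

  # blocking removes an intervention until its timer expires
  ivs[[5]]$blocked_until <- DAY0 + 1
  b2 <- list(id = "b", domain = "social", weights = c(calls_total = -1),
             interventions = ivs)
  rec2 <- recommend(ctx, list(b2), rng_draws = draws)
  expect_false("iv5" %in% vapply(rec2$baskets[[1]]$top, `[[`,
                                 character(1), "id"))

  # everything blocked -> basket flagged empty
  for (i in 1:5) ivs[[i]]$blocked_until <- DAY0 + 1
  b3 <- list(id = "b", domain = "social", weights = c(calls_total = -1),
             interventions = ivs)
  rec3 <- recommend(ctx, list(b3), rng_draws = draws)
  expect_true(rec3$baskets[[1]]$empty)
  expect_length(rec3$baskets[[1]]$top, 0)

  # exhausted baskets disappear until the next evaluation epoch
  rec4 <- recommend(ctx, list(b), exhausted_baskets = "b",
                    rng_draws = draws)
  expect_length(rec4$baskets, 0)
})

test_that("evaluation epochs advance every 6 hours on 00/06/12/18", {
  e0 <- evaluation_epoch(DAY0)
  expect_identical(evaluation_epoch(DAY0 + 6 * 3600000 - 1), e0)
  expect_identical(evaluation_epoch(DAY0 + 6 * 3600000), e0 + 1L)
  expect_identical(evaluation_epoch(DAY0 + 24 * 3600000), e0 + 4L)
})
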