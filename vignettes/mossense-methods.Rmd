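---
title: "mossense: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mossense: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mossense)
```

This vignette is the package's own account of what it computes, which
knobs matter, what the synthetic data generator does and does not
emulate, and where genuinely open design choices were resolved. It
states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The sensing model

All event streams live in a `subject_stream`: 2-minute accelerometer
activity windows, GPS fixes and WiFi scans at a nominal 15-minute
cadence, call/SMS logs, calendar events, phone lock/unlock intervals,
app sessions, and biweekly PHQ-9 self reports (integer 0–27, clinical
flag at ≥ 11). Timestamps are UTC epoch milliseconds; "per day"
statistics use the subject's clock through a configurable
`tz_offset_min` (default 0 — the source system never states a timezone
convention, so the package makes it explicit rather than implicit).

### Per-day behavioral proxies

*General activity* is the sample standard deviation of the
gravity-corrected acceleration norm over a window,
`sd(sqrt(ax² + ay² + az²) − 9.81)`. Subtracting the constant changes
nothing about the dispersion but is kept for fidelity to the published
form; because only norms enter, the statistic is invariant to any
rotation of the handset frame (property-tested). With 100 Hz per axis,
a window consumes 300 scalar samples per second. The *sample* (n−1)
standard deviation was chosen; the source does not say which
convention it used, and the walking threshold below is calibrated to
whatever convention is in force, so the choice is internally
consistent.

*Walking* is intensity-thresholded at 1.5 m/s² per 2-minute window,
boundary inclusive (the source states the threshold but not the
boundary convention; inclusive was fixed and documented). Each walking
window contributes 2 minutes.

*Time at home* relies on a WiFi fingerprint learned from the first
three consecutive nights (local 00:00–05:00, configurable) whose
nightly BSSID sets overlap pairwise with Jaccard ≥ 0.5 — "reasonable
overlap" quantified, since no number is published. The fingerprint is
the three-night intersection. A daytime scan counts as at-home when it
intersects the fingerprint (rule `"any"`; a minimum-fraction rule is
available), contributing 15 minutes per matching scan. When learning
fails, time at home is *missing*, not zero — the deployed system would
fall back to asking the user.

*Mobility*: total distance is the sum of consecutive-fix haversine
distances on a spherical Earth (R = 6 371 000 m); maximum distance is
the largest *pairwise* distance (an anchor-based alternative was
considered; pairwise was chosen and is the documented convention).
Location variance is `log(pop.var(lat) + pop.var(lon))` in degrees²,
floored at `log(10⁻¹²)` for days without movement so the statistic is
defined rather than erroring.

*Phone use* sums unlocked intervals clipped to the day, minus in-app
seconds pro rata. *Communication* and *calendar* counts are plain
tallies with unique contacts merged across directions.

### Missingness semantics

Sensors differ in what absence means. Continuous sensors
(accelerometer, GPS, WiFi, phone state) are missing on any day without
events. Event logs (communication, calendar) are zero-and-observed on
quiet days, missing only when the subject-level stream is entirely
empty — a silent phone is data, an unlogged phone is not. A day with no
events in *any* stream is treated as unobserved and fully masked (this
also resolves a corner where the two rules would disagree). Every
`DayFeatures` value carries a `__mask` flag; masked values are excluded
from aggregation and imputed (training-fold median) only at modeling
time.

## 2. The 120-dimensional descriptor

For each PHQ-9 record preceded by 14 fully-enumerated calendar days,
each of 24 base features is summarized by mean, sum, population
variance, min and max over its unmasked days: 24 × 5 = 120, in a fixed,
regression-tested order. The published count (120 = 24 × 5) does not
enumerate the roster; this package's roster is the 18 directly measured
features plus six derived ones (`sms_total`, `calls_total`,
`comm_unique_contacts_total`, `cal_total`, `dist_per_fix`,
`home_fraction`) and is an explicit package decision, not a claim about
the original system. A base feature with fewer than `min_valid_days = 7`
unmasked days is masked wholesale (its 5 statistics become `NA`); a
vector with more than `max_masked_features = 4` masked base features is
dropped. Both limits are package choices on a question the source is
silent about, set so that a subject must be sensed for at least half
the window to be scored.

## 3. Detection protocol

Folds are subjects ("leave one subject out"): all rows of the held-out
subject are predicted by a model fitted to everyone else, and metrics
are pooled over held-out predictions. Imputation medians and
standardization means/sds come from the training folds only — audited
in tests by comparing per-fold statistics against hand-computed
training-only values. Standardization before the RBF SVM is an assumed
step (kernel widths are meaningless across raw feature scales); the
source does not state it.

The random forest (450 trees by default, `mtry = ⌊√p⌋`, gini CART grown
to purity on bootstrap samples) and the SMO-trained RBF SVM are
implemented in C++ inside the package because the deployment
environment guarantees no forest/SVM library. The SVM's cost and kernel
width are optimized per fold by Nelder–Mead over `(log₁₀C, log₁₀γ)`
starting at `(0, log₁₀(1/120))`, the objective being inner grouped
5-fold CV accuracy on the training folds — the optimizer is named in
the source, the objective and initialization are not, so they are
package decisions. Class imbalance is left unweighted, matching the
reported protocol.

Two determinism guarantees worth noting: every stochastic element is
keyed to an integer seed, and `loso_cv` canonicalizes row order
internally (subject, then feature values) with fold seeds keyed to
subject ids, so results are invariant to the order rows arrive in —
without this, the bootstrap RNG would make "the same data, shuffled"
give different forests.

## 4. Recommender

Baskets of interventions are scored every 6 hours (boundaries at local
00/06/12/18 — the period is published, the phase is a package choice)
as a weighted sum of range-scaled context features over the trailing
24 h. `scale_to_range` clamps to [0, 1]. The per-basket feature weights
were hand-set by clinicians in the original system and are not
published; the shipped catalog (`default_catalog()`) encodes the
intended directions (e.g. the physical basket's weight on walking is
negative, so sedentary days raise its score) and is plain, overridable
data.

Phase 1 uses population assumption ranges — time at home 7–14 h/day,
calls 0–6/day, walking 30–300 min/day, plus package defaults for the
other scored features where only directions are established. After two
weeks, phase 2 replaces them with the subject's own last week:
μ ± 2σ per feature, widened to a minimum width when a week is constant
(σ = 0 would otherwise collapse the range), clipped below at 0 for
counts. When a subject's week exactly matches the population mid-range,
phase-2 scores reproduce phase-1 scores (consistency-tested).

Within a presented basket, eligible (home/away and time-slot rules) and
unblocked interventions are ranked by
`0.75·meanRating/5 − 0.25·cancelRate + 0.5·[u ≤ 0.05]` and the top 3
shown. Readings fixed here on silent points: "past ratings" is the mean
of all ratings in the intervention score but the *last* rating in the
block timer `36·(6 − rating)` hours, per the two formulas' own legends;
the cancellation-rate denominator is total attempts (executions +
cancellations); unrated interventions use a neutral prior of 3 stars
with rate 0; the chance bonus is drawn per intervention per evaluation
(injectable in code, so tests are deterministic); neglected
interventions count as neither execution nor cancellation.

## 5. The synthetic cohort: what a green test establishes

The generator is a *stated world*, not a tuning dial. Severity (PHQ-9
scale) maps linearly between two daily-behavior anchors — healthy
(severity 0): 6 h at home, 320 min walking, 7 calls; severe
(severity 27): 15 h, 25 min, 0 calls — bracketing the published
population assumptions (< 7 / > 14 h, > 300 / < 30 min, > 6 / 0 calls).
Magnitudes with no published anchors are admitted inventions fixed
once: texts 9→1/day, phone use 2→4.5 h/day (rising with severity, in
line with the phone-use literature the source builds on), calendar
events 3→0.5/day, away-excursion spread 0.05→0.005°, day-level Gaussian
noise scales in `.day_noise_sd`, and discretized-Gaussian PHQ-9
observation noise with sd 2 points. Days are structured so nights
(00:00–05:00) are always at the home fingerprint — home learning has
its three nights by construction. Dropout is epoch-wise: everyone
completes the baseline 2-week epoch, then leaves with the configured
hazard after each completed epoch.

With `noise = 0` the generator is deterministic at the daily-target
level, and the feature extractor recovers time at home, walking minutes
and call counts *exactly* — the strongest oracle the package has, and
the basis of the parameter-recovery acceptance check.

What the simulator does **not** emulate: raw accelerometer waveforms
(windows are generated directly at the `stdev_norm` level; the raw-path
statistic is tested separately on synthetic samples), GPS drift and
urban canyon artifacts, WiFi scan dropouts, non-stationary daily
routines (weekends, travel), missing-not-at-random sensor gaps, or any
treatment effect of the interventions on severity. Consequently, a
green classification test establishes that the *pipeline* is correct
and leak-free — that separable behavior yields separable vectors and
LOSO finds them, and that permuted labels collapse accuracy to
chance — not that real phones yield the published accuracy. The
published headline numbers depend on undeposited participant data and
are deliberately not targets.

## 6. Evaluation statistics

Adherence bands: left before week 2; weeks 2–4; ≥ 4 weeks with ≥ 2
post-baseline questionnaires; and a residual band for long adherers
with too few questionnaires (the published proportions cover 118/126
subjects; the residual 8 are only consistent with this reading).

The progression test synchronizes every subject's baseline t0 at their
first PHQ-9 record and runs a Wilcoxon signed-rank of t0 against each
later biweekly horizon, differences taken `t0 − tn` so improvement
gives positive z. Zero differences are dropped (the original
convention); p is exact (signed-rank null distribution) for ≤ 25
tie-free pairs and a tie-corrected, continuity-corrected normal
approximation otherwise; the reported statistic is always the normal
deviate, as in the field's tables. A Kolmogorov–Smirnov normality check
of the paired differences is recorded alongside — the rationale for
preferring a rank test. The usage–symptom analysis is a Spearman
correlation (midranks; t-approximation p on n − 2 df) between
qualifying sessions — sessions with at least one intervention
executed — and `PHQ9(t_end) − PHQ9(t0)`.

## 7. Numerical and degenerate-input choices

- Variances are population (÷ n) in day-feature aggregation and
  location variance; the μ ± 2σ personalization uses the sample sd, as
  "the standard deviation of the last week" conventionally means.
- `loc_var` floor 10⁻¹² deg²; degenerate personalization ranges widened
  to `min_width = 1`; zero-call days have `avg_call_duration_s` masked
  rather than fabricated as 0-and-observed.
- Basket score ties break by basket id; intervention ties by id —
  deterministic output for equal scores.
- Single-class training folds are skipped with a warning; if skipping
  removes a class from the pooled truth, metrics are `NA` rather than a
  misleading number.
- All seeds stay below 2³¹; per-subject and per-fold seeds are derived,
  not shared, so subjects are independent streams under one master
  seed.

## 8. Known limitations

Linear severity–behavior coupling with Gaussian day noise is the
simplest model consistent with the stated anchors; real behavior is
heavier-tailed and autocorrelated. Home learning assumes the subject
sleeps at one home during the learning window. The SMO implementation
targets the small-n regime of this problem (hundreds of rows); it is
not tuned for large datasets. The recommender's weights are
illustrative defaults, not clinically validated values. The evaluation
module reproduces the *protocol* of the single-arm analysis; nothing in
it supports causal claims about intervention efficacy, in the synthetic
world or outside it.
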