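---
title: "Methods: daily scoring for Parkinson disease home monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: daily scoring for Parkinson disease home monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parkscore)
```

`parkscore` converts six raw home-monitoring event streams for a person
with Parkinson disease into one row of 0–100 scores per calendar day and
provides the rolling, banded and correlational views built on that table.
This vignette is the package's own account of the scoring model: what each
score assumes, which thresholds matter, where the design was genuinely
open and what the synthetic scenarios do and do not establish.

## Time model

All timestamps are minute-resolution, timezone-naive local time (stored as
UTC-pinned `POSIXct`, so arithmetic never crosses a daylight-saving
boundary). Every point event — dose, motor sample, meal, exercise report,
questionnaire response — belongs to the calendar date containing its
timestamp. The one deliberate exception is sleep: a night usually spans
midnight, so bed intervals are first chained into *sleep episodes*
(consecutive intervals separated by less than `night_chain_gap_h = 4`
hours) and each episode is attributed to its **wake day**, the date of the
final leave. An episode only counts as a night if it starts after 18:00 or
before 12:00; early-afternoon episodes are treated as naps and are not
scored, because an afternoon nap says little about the night's sleep
quality and would otherwise displace it. Both thresholds are configurable;
the attribution convention itself is a package choice — the monitoring
protocol defines the in-bed window via first entry and next-morning leave
but never assigns the night to a day.

## Medication compliance

The dosing device yields planned intake times and delivered intakes, the
latter labelled scheduled-delivery or extra. Scoring proceeds in three
steps.

**Matching.** Scheduled deliveries are paired with planned intakes, at
most one each, by the assignment minimising the total absolute timing
deviation. Because the cost is an absolute time difference, some optimal
assignment never "crosses" when both lists are sorted, so a small
dynamic program over the two sorted lists finds it exactly; ties are broken
toward the earlier delivery. We preferred the optimal assignment over
greedy nearest-neighbour matching because greedy provably mis-pairs
interleaved patterns (planned 08:00/09:00, delivered 08:55/09:05 pairs
08:55→09:00 first and strands 09:05 at 08:00) and the exhaustive
small-instance oracle in the test suite would catch exactly that.

**Extra-dose classification.** An extra dose within
`replacement_window_min = 30` minutes of a planned time is a *replacement*:
if that planned intake is otherwise unmatched the extra becomes its
delivery (status `replaced`); if the intake was already delivered the
extra is omitted from all calculations. An extra outside every window is
an *extra-credited* occasion, scored 100 — the patient medicated when they
judged they needed to. A scheduled delivery beyond the planned schedule
(rare, e.g. a delivery drifting across midnight) is classified by the same
rules as an extra.

**Scoring.** Per occasion: extra-credited → 100; missed → 0; otherwise the
deviation `|Δt|` in minutes maps to `max(0, 100·(1 − |Δt|/D))` with
`D = deviation_max_min = 120`. The daily score is the arithmetic mean over
occasions; no occasions → missing. The protocol's description fixes the
endpoints of this mapping — deviations in minutes, scores 0 to 100, extras
at 100 — but not its printed functional form, so the package uses the
simplest monotone linear decay and isolates it behind one function and one
configuration key. Scoring a missed intake 0 (rather than dropping it) is
likewise a package decision: dropping it would let skipped doses *raise*
the daily mean. Whether a replacement contributes its own deviation or is
omitted from the mean entirely is ambiguous; both behaviours ship behind
`replacement_counts` (`"deviation"`, the default, or `"omit"`).

## Sleep

Three components adapted from the Pittsburgh Sleep Quality Index are
graded 0 (best) to 3 (worst) per night:

| component | input | 0 | 1 | 2 | 3 |
|---|---|---|---|---|---|
| duration | cumulative hours in bed | > 7 | 6–7 | 5–6 | < 5 |
| efficiency | 100·cumulative ÷ (first entry → final leave), % | ≥ 85 | 75–85 | 65–75 | < 65 |
| disturbances | interruption count | 0 | 1 | 2 | ≥ 3 |

The protocol's duration and efficiency rules use strict inequalities that
leave the exact boundary values (7, 6, 5 hours; 85, 75, 65 percent)
unassigned; here a boundary joins the less-severe bucket (exactly 7 h
grades 0, exactly 75 % grades 1), a benefit-of-the-doubt rule chosen for
determinism. Gaps shorter than `min_interruption_gap_min = 1` minute are
merged as bed-sensor jitter before counting interruptions. The daily score
is `100·(1 − (c₁+c₂+c₃)/9)`, the linear complement of the component sum
scaled to 0–100 — again the simplest mapping consistent with the protocol's
0-to-100, higher-is-better scale, with the efficiency-ratio form being the
standard PSQI habitual-efficiency definition. A night whose in-bed window
has zero length is a degenerate-night error rather than a silent 0 or 100.
If two qualifying episodes wake on the same day, the longer one is scored.
Daytime naps do not enter cumulative hours (see the nap rule above).

## Motor function

The wrist sensor emits bradykinesia and dyskinesia estimates every 2
minutes, assumed pre-normalised to 0–100 with higher = better, consistent
with every other daily-summary variable. The daily summary is the
per-channel arithmetic mean over the day's valid samples, and the two
channels are always reported separately. All samples enter the mean,
including nighttime ones — the protocol is silent on exclusion, and
excluding sleep hours would entangle the motor score with bed-sensor
availability. A day without samples is missing, never 0.

## Meals, exercise, quality of life

**Meal timing.** Each levodopa intake (scheduled or extra) defines a
protected window from `meal_window_before_min = 30` minutes before to
`meal_window_after_min = 60` minutes after it. The protocol's phrase
"recommended meal intake time (30 minutes before and 60 minutes after
medication intake)" does not state on which side of the window a meal
should fall. The default reading here is **avoid**: a meal complies when
it falls inside *no* intake's window, because dietary protein competes
with levodopa for intestinal absorption and the clinical advice is to keep
meals away from doses. The opposite reading ships behind
`meal_window_mode = "require"`. The daily score is `100·NWI/n` over the
day's reported meals; window edges belong to the window.

**Exercise.** The protocol's worked example — mode 1 for 10 minutes plus
mode 2 for 25 minutes against a target of 80 scoring 75 — fixes the
formula as a mode-weighted minute sum normalised by the individual
target: `min(100, 100·Σ mode·duration / target)`. (The accompanying prose
mentions an "average score per day", which contradicts the example; the
numeric example is the only verifiable anchor, so the sum is used.) The
cap at 100 keeps the shared scale; the target lives in (0, 100].

**Quality of life.** Nine items daily: eight 3-level items (five EQ-5D-3L
dimensions, three PDQ-8 items; see `qol_items()`) recoded by
`item_score = 3 − level` to the clinician tile scale 0–2 with 0 worst, and
the EQ-5D-3L 0–100 visual-analogue overall-health rating. The patient
start page's "overall day score" is given no formula anywhere, so the
package takes the VAS — the only self-contained 0–100 overall measure in
the data — as the overall day score. No EQ-5D utility tariff or PDQ-8
summary index is computed.

## Aggregation views

`rolling_summary()` averages each score over the trailing
`rolling_window_days = 14` days, excluding missing days score-by-score.
`classify_score()` bands a value as good (> 70, green), average (30–70,
gray) or bad (< 30, orange); 30 and 70 themselves are average, following
the protocol's "30 to 70" middle band. `correlate_scores()` pairs score *x*
on day *d* with score *y* on day *d + lag* over pairwise-complete days and
reports Pearson's *r* by default (Spearman by flag — the evaluation
request named no method, and daily scores are near-continuous); fewer than
three complete pairs is an explicit insufficient-data error. Days without
any data keep an all-missing row so the time axis stays contiguous and
window arithmetic stays honest.

## The scenario simulator

`simulate_scenario()` emulates the six streams with controllable adherence
noise, missed and extra doses, interrupted nights, dose-locked motor
fluctuation and missing-data patterns. Defaults describe a plausibly
adherent monitored patient over 14 days — the standard dashboard window:
three daily doses at 08:00/14:00/20:00, timing deviations of SD 15 minutes
truncated at 3 SD, a 5 % miss probability, 0.2 extra doses/day, 8 hours in
bed from about 23:00 with Poisson(1) interruptions of 5–20 minutes, motor
baseline 70 with a raised-cosine post-dose response (amplitude +15 on
bradykinesia and −7.5 on dyskinesia over 120 minutes — the simplest shape
that makes the dose→motor coupling detectable by correlation), sample
noise SD 5, three meals, 70 % exercise days and a VAS around 70. One
master seed yields per-stream sub-seeds, so tweaking one stream's
parameters never perturbs another stream's draws, and identical seeds
produce byte-identical written scenarios.

The generator records its realised ground truth (per-day mean absolute
timing deviation, night structure, noise-free motor means, compliant meal
fractions). Recovery tests check the engine against that truth and against
closed forms — e.g. the mean absolute deviation of a centred Gaussian,
`σ·√(2/π)`, within 3 standard errors over 100 simulated days. Test
problem sizes are deliberately modest: 100-day recovery runs, 1000
one-day stress scenarios spanning extreme configurations for range
conservation, 25 seeded 28-day runs for the correlation sign, and
exhaustive oracles only on instances of up to five doses or ten
meal events, where enumeration is exact.

What the simulator does *not* claim: clinically realistic Parkinson
phenotypes. There is no disease progression, no wearing-off
pharmacokinetics, no circadian structure in the motor signal beyond the
dose response, and interruption lengths are uniform rather than fitted to
actigraphy. Passing tests therefore demonstrate that the scoring engine
implements its stated rules and recovers known statistical structure — not
that the scores are clinically valid on real device data.

## Numerical and degenerate-input choices

* Timestamps are floored to whole minutes on parsing; all deviations are
  whole minutes, so no score depends on sub-minute arithmetic.
* Planned intakes less than one minute apart are a validation error (the
  matcher's deviations would be ambiguous at minute resolution).
* Empty streams are valid everywhere and propagate as missing scores,
  never as zeros; every `NA` in the daily table means "not observed".
* Matching tie-breaks (earlier delivery preferred) and the
  boundary-bucket rules above make the whole pipeline deterministic:
  identical inputs and configuration give byte-identical outputs.

## Limitations

The engine scores timing compliance only — dose *amounts* are carried but
not scored, matching the protocol's definition. The deviation-decay and
final-sleep-score mappings are reconstructions pinned only at their
endpoints; if the originally deployed equations surface, they drop in
behind `occasion_score()` and `daily_sleep_score()` without touching the
rest of the pipeline. Raw-sensor calibration (accelerometry to
bradykinesia estimates, bed-sensor debouncing beyond the minimum-gap rule)
is out of scope, as are the patient and clinician user interfaces
themselves.
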