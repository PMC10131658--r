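---
title: "Anchoring wrist-derived activity intensity to ankle-detected walking: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{walkanchor methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walkanchor)
```

## The measurement problem

A wrist accelerometer converts arm movement into an activity-intensity
estimate; walking, however, is made by the legs. Whenever the arm is
decoupled from gait — a walker or cane, a hand on a cart, carrying,
age- or disease-related reduction of arm swing — the wrist under-reports the
true intensity of walking, sometimes to the point of labelling a brisk walk
*sedentary*. `walkanchor` quantifies that failure mode by pairing the wrist
with an ankle device: the ankle declares *when* the person walks, and the
wrist's intensity estimate is evaluated only inside those known walking
periods.

The analysis makes three assumptions worth keeping explicit:

* **The ankle is ground truth for stepping.** Ankle accelerometry is robust
  across gait styles and speeds, and crucially is *insensitive to arm
  behaviour* — the manipulation under study.
* **Sustained, brisk walking is at least moderate activity.** Restricting
  analysis to LONG walks (≥ 60 s, median cadence > 80 steps/min) selects
  purposeful locomotion for which a sedentary wrist label is, by
  construction, a misclassification.
* **Intensity cut points are a transferable configuration.** The pipeline
  applies thresholds to 15-s wrist AVM epochs; the thresholds themselves
  are study inputs, not outputs.

## Signal processing

**Calibration.** Stationary windows (default 10 s, all-axis SD below
0.013 g) should measure exactly 1 g. An iterative sphere fit alternates
per-axis regressions of the unit-sphere projection on the window means,
yielding per-axis gain and offset. Calibration is refused (identity
returned, flagged) when fewer than 5 stationary windows exist, when all
window orientations lie within 30° of each other (an under-determined fit),
or when the fitted parameters leave the plausible ranges (gains in
[0.8, 1.2], offsets within ±0.25 g). A refused calibration is never an
error: downstream stages run uncalibrated and say so.

**AVM epochs.** Axes are low-pass filtered (4th-order Butterworth, 20 Hz,
zero-phase; skipped when the Nyquist frequency does not exceed the cutoff —
20 Hz preserves all gait content at both 50 and 75 Hz), then the per-sample
Euclidean norm minus 1 g, truncated at zero (ENMO), is averaged over 1-s
epochs and reported in milli-g. Filtering precedes gravity subtraction;
the order is configurable since the alternative is equally defensible.
1-s epochs are reaveraged into 15-s epochs by plain arithmetic means, so
the sum of value × duration over the retained span is conserved exactly.
Trailing partial epochs are dropped, never padded. All zero-phase filtering
uses odd-reflection end padding: bare `filtfilt` leaves edge transients
even on constant input, which an AVM-must-be-zero-at-rest oracle exposed.

**Nonwear** is flagged where at least 2 of 3 axes are simultaneously
near-constant (SD < 0.013 g and range < 0.05 g per 60-s window) for at
least 60 min, with candidate intervals merged across gaps shorter than
5 min. These are conventional parameter values; the detector is
deliberately simple and its defaults are configuration.

**Sleep** uses a pass-through for external annotations, else a heuristic:
the longest run of ≥ 5 h within each 20:00–12:00 search window whose
5-min rolling median of 1-s AVM stays below 5 mg. Replicating a published
sleep algorithm is out of scope; sleep affects only valid-day accounting,
not the LONG-walk analysis.

**Step detection.** The anteroposterior axis is auto-selected as the
non-gravity axis with the most 0.5–3 Hz power, band-passed to 0.5–3 Hz, and
local maxima above an adaptive threshold become steps (0.25-s refractory,
larger peak wins a conflict). Two numerical details matter. First, the
threshold is `max(0.02 g, 0.7 × rolling median |signal|)` per 10-s block:
after narrow band-passing, walking is quasi-sinusoidal, and the median
absolute amplitude of a sinusoid is ~0.71 of its peak — so any multiplier
above ~1.4 on that statistic (e.g. a textbook 3×MAD rule) sits *above every
peak* and detects nothing; 0.7 places the threshold at about half the local
amplitude, while the absolute 0.02 g floor rejects noise and postural
fidgeting when no walking is present. Second, peak times are refined by
parabolic interpolation through each peak and its neighbours; without
sub-sample timing, inter-step intervals quantize to the sample grid
(0.02 s at 50 Hz) and bout cadence medians can be off by over 2 steps/min.

**Bouts and flags.** Steps with inter-step gaps ≤ 5 s (inclusive — a
"maximum rest of 5 s" is a permitted maximum) form a bout; bout boundaries
are the first and last step times with no padding. Instantaneous cadence is
60 / inter-step interval and a bout's cadence is the median over its
pairs — robust for short bouts and faithful to a median-based summary.
LONG requires duration ≥ 60 s *and* median cadence strictly above
80 steps/min ("above 80" read as strict; a boundary test pins the choice).
ALL requires ≥ 5 steps.

## Epoch–walk intersection and classification

The 15-s epoch grid is anchored at the recording start and global across
the day (the natural reading of reaveraging a continuous stream); it is
*not* re-anchored per walk. An epoch belongs to a walk iff it starts at or
after the walk's start and ends at or before the walk's end — epochs
running past the walk's end are excluded, and the first candidate epoch is
the first grid epoch starting inside the walk. Only the end rule is
prescribed by the analysis this package implements; start handling is the
package's documented symmetric choice. The implementation is verified
against a brute-force interval-containment oracle over 1000 random
walk/grid offsets.

Classification is lower-inclusive for the upper class: AVM exactly at a
threshold takes the higher label ("above the moderate threshold" is
ambiguous at equality; the choice is fixed and tested). Raising the light
threshold can only grow the sedentary count; raising the moderate threshold
can only shrink MVPA — monotonicity is property-tested.

The shipped cut points (light at 30 mg, moderate at 100 mg of 15-s AVM) are
**placeholders calibrated to the synthetic generator**. The published
older-adult wrist cut points this design would use in production are not
reprinted here; deployments must transcribe them into the configuration,
and the `provenance` field exists so nobody mistakes defaults for
literature values.

## Statistics

Epochs are dichotomized sedentary vs active (light + MVPA merged — the
conservative direction: only outright "sedentary walking" counts as
misclassified). Per participant, a Fisher exact test compares the observed
split with the expectation that all LONG-walk epochs are active. The
expected distribution is realized as the 2×2 table
`[[n_active, n_sedentary], [n, 0]]` — an equal-sized pseudo-group with zero
sedentary epochs, the only table faithful to "expected all active". This
construction is stated prominently because the sentence it implements does
not specify the layout. The two-sided p sums hypergeometric probabilities
no larger than the observed table's; the implementation (via
`stats::fisher.test`) is verified against full enumeration for all totals
≤ 50. The Bonferroni family is one test per participant (m = cohort size;
35 in the motivating design).

Sedentary-misclassified minutes are epoch count × 0.25; the clinically
important threshold (20 min ≈ one day's worth of a 150-min weekly MVPA
recommendation over a week of wear) is inclusive at exactly 20.0.

Quartile stratification sorts participants by percent-sedentary and takes
the extreme groups of size ⌈n/4⌉ (9 of 35 reproduces the motivating
design's group size), with ties broken by participant id for determinism.
Group comparisons use pooled-variance two-sample t tests,
df = n₁ + n₂ − 2; with zero pooled variance, equal means give t = 0 and
unequal means are flagged infinite. The AVM coefficient of variation is the
sample (n − 1) SD over the mean, × 100, pooled over all of a participant's
15-s LONG-walk epochs (per-walk-then-average was the alternative; pooled is
the package's documented choice). Fisher counts use the post-exclusion
epoch set — the same analysis set everything else summarizes.

## The synthetic generator

`simulate_participant()` renders a behavioural profile into wrist and ankle
recordings plus a ground-truth ledger (step times, bout intervals and
cadences, per-epoch expected conditions and labels, sleep/nonwear).

* **Ankle steps**: at cadence-defined times with 2% timing jitter, a damped
  8 Hz ringing (~0.8 g) plus a unidirectional half-sine strike component.
  The strike term exists because a pure zero-mean 8 Hz burst train carries
  only ~0.05 g at the step fundamental — physically implausible (foot
  strike has a net deceleration spike) and too weak for any 0.5–3 Hz
  detector; with it, the step-rate spectral line is ~0.13 g.
* **Wrist, normal swing**: a sinusoid at stride frequency (cadence/120 Hz —
  arms swing once per stride) with the profile's amplitude, split between
  the gravity axis and a perpendicular axis. At the default 0.4 g and
  ~107 steps/min this yields ~130 mg epochs (MVPA under the shipped cuts).
* **Suppressed / ADL**: zero swing; the ADL posture additionally reorients
  static gravity (horizontal forearm, palm down). Walk-time wrist AVM then
  reflects only sensor noise (< 10 mg → sedentary).
* **Tremor**: suppressed swing plus a 4.5 Hz pronation–supination sinusoid
  (default 0.35 g → ~110 mg → MVPA), matching the clinical observation that
  tremor can masquerade as activity.
* **Context**: waking non-walk time is low-amplitude fidgeting — a
  rectified slow oscillation (default 0.03 g) chosen so sedentary waking
  epochs sit clearly between the sleep-quiet level (< 5 mg) and the light
  cut point; sleep is near-zero motion with brief two-axis position turns
  every 15–25 min (so sleep does not read as nonwear); nonwear is an
  exactly constant orientation with zero noise, unambiguous by design.
  White sensor noise (0.01 g) covers everything worn.

Scenario presets (`active_oa`, `gait_aid` with 90% of walks suppressed,
`tremor_pd`, `mixed_adl`, and `graded` for dialling an expected sedentary
fraction directly) draw per-participant parameters deterministically from
one seed per participant.

What the generator does *not* emulate: realistic ADL taxonomies beyond arm
posture, energy expenditure, spatial gait parameters, device clock drift
(beyond what `synchronize()` corrects), temperature effects, or the
short-fragmented-bout structure that dominates real free-living walking.
Passing recovery tests on this generator therefore demonstrates the
pipeline's internal correctness — that each stage measures what the ledger
says was rendered — not field accuracy of the step detector or cut points
on real devices.

## Degenerate inputs and tie-breaks

Empty step sets, bout-less recordings, zero-epoch participants and
zero-mean CoV inputs return empty/`NA` results with flags or warnings, not
errors. A gap of exactly 5 s stays within a bout; a 20.0-min sedentary
total exceeds the clinical threshold; an epoch exactly at a cut point takes
the higher class; quartile ties resolve by id. Calibration applied twice is
idempotent within 1e-6 g, and AVM is invariant to fixed rotations of the
device frame (both property-tested).

## Problem sizes in the test suite

The suite exercises: 2-h participants at 50 Hz for cohort recovery (12
participants, graded sedentary fractions 0.05–0.55), one 24-h participant
for the sleep/nonwear/valid-day path, 1000 random offsets for the
epoch-containment oracle, and cadences 80–140 steps/min crossed with
normal/suppressed/tremor arm conditions for step-count recovery (error
≤ 3% required). These sizes were chosen as the smallest that exercise every
code path with comfortable statistical margins.

## Known limitations

* The step detector is a transparent band-pass/peak-picking design,
  adequate for the synthetic acceptance surface; production use on real
  ankle data would warrant validation against annotated gait.
* The sleep heuristic is deliberately crude; misestimated sleep moves only
  daily wear accounting, never LONG-walk statistics.
* Clock-drift correction is linear through at most two anchors; recordings
  without anchors are assumed drift-free.
* The EDF writer/reader implements the subset of the format the package
  emits (three ±8 g signals, 1-s records, 16-bit), with the true sample
  count kept in a reserved header field so partial trailing records
  round-trip; exotic EDF produced elsewhere may not read.
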