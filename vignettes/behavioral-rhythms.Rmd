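---
title: "Behavioral rhythms from smartphone passive sensing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral rhythms from smartphone passive sensing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmgrid)
```

## The problem

Lay counselors delivering behavioral-activation therapy to young mothers with
postpartum depression have no objective window into their clients' week: how
much time a mother spent with her infant, whether she was physically active,
whether there was conversation around her, whether she left the house. A
smartphone carried by the mother can sense all four passively — Bluetooth
scans for a beacon on the infant's clothing, accelerometer-based activity
recognition, a 30-second audio clip every 15 minutes classified into sound
classes, and GPS fixes whenever the phone is used. `rhythmgrid` turns those
raw per-day log files into the hour-level behavioral summaries a counselor can
discuss in session: daily rhythm codes, mobility metrics, and automated
motivational awards.

## The data model

Every sensor stream is first quantized to a **96-bin 15-minute daily grid**
with an explicit missing state. Bin $k$ covers the half-open interval
$[15k, 15(k+1))$ minutes from local midnight; a bin with no records is
*missing*, never imputed. Keeping missingness explicit is what makes day-to-day
rhythm comparison honest: sensors are not collected simultaneously, and an
hour without data must be distinguishable from an hour of observed stillness
or separation.

All timestamps are the participant's local clock (ISO-8601 without a zone):
the object of study is the daily schedule, and a 13:00 separation means 13:00
on the mother's clock regardless of zone bookkeeping.

## Hour coding rules

Each hour (4 consecutive bins) of each channel is coded by an
*at-least-one-reading* rule:

* **Proximity** — `together` if any completed Bluetooth scan in the hour
  detected the infant's beacon; `apart` if scans completed but none detected
  it; `no_data` otherwise. Distinguishing `apart` from `no_data` requires the
  collector to log completed scans without detection; a store holding only
  detections degrades to {`together`, `no_data`}.
* **Activity** — `active` if any reading in the hour is not-still (walking,
  running, in_vehicle, cycling); `inactive` if readings exist but every
  observed label is `still`. `unknown` labels are evidence of nothing: an
  hour with only `unknown` readings is `no_data`, because "inactive" means
  *observed* stillness.
* **Speech** — `speech` if any 30-second clip in the hour carries a
  speech-class label with prediction score at or above the threshold
  (default classes `{"Speech"}`, threshold 0.5; both configurable, since
  audio classifiers differ in vocabulary and calibration); `no_speech` if
  clips exist but none qualifies; `no_data` with no clips.

The daily **speech count percentage** is the share of the day's clips that
qualify as speech (a multi-label clip counts once); it is missing on a day
with no clips.

By construction the three per-channel state counts each sum to 24 on every
coded day, and adding a qualifying record to an hour can only move its code
toward the positive state — both properties are enforced in the test suite.

## GPS mobility features

* **Home** is estimated as the centroid of the modal occupied heat-map cell
  among night-window fixes (00:00–06:00), falling back to the modal all-day
  cell when no night fix exists. The night window and the 100 m home radius
  are standard digital-phenotyping conventions, both configurable.
* **Radius of movement** is the radius of gyration: the RMS great-circle
  distance of the day's fixes from their spherical centroid. A single fix has
  radius 0; two fixes $d$ apart have radius $d/2$.
* **Farthest distance traveled** is interpreted as the maximum distance from
  home. Cumulative path length was deliberately excluded: fixes are
  event-driven (phone use) and irregular, so a path-length estimate would be
  dominated by the sampling pattern rather than by movement.
* **Fraction of time outside the home**: among 15-minute bins containing at
  least one fix, the fraction whose last fix lies more than the home radius
  from home. Conditioning on observed bins avoids pretending to know where
  the mother was when the phone was idle.
* **Heat maps** are plain count grids over the fixes' bounding box at a
  default cell of 0.0005° (~55 m) — fine enough to resolve within-village
  movement, coarse enough that a night of fixes lands in one cell. Rendering
  is left to the caller (`plot()` draws a basic image); only the count-grid
  semantics are reproducible.

Distances use the haversine formula on a sphere of radius 6,371,000 m.

## Award rules

Awards operationalize behavioral-activation goals as explicit predicates: a
channel, a statistic (`hours_in_state`, `speech_pct`, `fraction_outside`), a
comparator and a threshold, evaluated per day or per week. The shipped
defaults — speech present during the day, ≥ 4 active hours, ≥ 8 together
hours, left home (fraction outside > 0) — cover the social-interaction,
daily-routine and self-care goal categories; the thresholds are package
defaults, not clinical recommendations, and every deployment should supply
its own rule config and message catalog. Week-window rules needed one field
beyond the day predicate: `min_days`, the number of qualifying days required
(default 1). Re-evaluating a period is idempotent, and `≥`-rules are monotone
under added qualifying hours, so an award once earned cannot be revoked by
more data.

## The simulator

`schedule_config()` defines a latent daily routine — home location, trips
(with destination offsets), mother–infant separation episodes, speech
episodes (per-clip speech probability), activity bouts — and `simulate_day()`
samples it the way the collector app would:

* proximity scans, activity readings and audio clips on a 15-minute cadence;
* GPS fixes at phone-use events, a Poisson process at 4/hour while awake
  (06:00–22:00) and 0.2/hour at night, with ~8 m Gaussian position jitter
  (typical phone fix accuracy — small against the 55 m heat-map cell);
* audio clips restricted to a 10-hour daytime capture window (08:00–18:00 by
  default). The cadence alone would imply 96 clips/day, while a realistic
  collector produces roughly 40; the window resolves that tension explicitly
  and configurably, and makes the default week emit exactly 40 clips/day and
  280/week.

**Dropout is modeled as sensor outages**: each (sensor, hour) independently
loses all its records with the configured rate. Real collection gaps are
contiguous — a phone switched off, an app killed — not independent
record-level coin flips; and outage-style loss gives the recovery guarantee
its sharp form: a surviving hour codes exactly its true label, a dropped hour
codes `no_data`, and no amount of dropout can fabricate a wrong observed
state. (Under independent per-record loss that guarantee is impossible: an
hour whose detections are all dropped but whose undetected scans survive
would code `apart` against a `together` truth.)

Ground truth is the realized truth of the day: the per-hour labels a perfect
coder would derive from the complete pre-dropout record stream (speech is
stochastic per clip, so truth must reflect the draws), computed directly per
hour without the 15-minute grid, plus the true home and the realized
outside-home fraction. Identical seeds give byte-identical output; each day's
seed derives from the config seed and the date, so any single day is
reproducible in isolation.

What the simulator does **not** emulate: GPS noise beyond small jitter (no
urban-canyon multipath), beacon RSSI physics (detection is a clean function
of the separation schedule), classifier confusion structure in the audio
labels, infant-side sensors, and waveform-level audio. Passing recovery tests
therefore demonstrates the pipeline's correctness on well-formed logs, not
robustness to adversarial sensor noise.

## Numerical and degenerate-input choices

* Bins and hours are half-open; the day boundary is local midnight.
* Zero records: grids are all-missing, coded days are all-`no_data`, speech
  percentage and mobility metrics are `NA` (never 0 — absence of evidence).
* A sensor file with more than half its rows malformed is rejected as
  corrupt; below that, bad rows are skipped and counted in a parse report.
* Duplicate suppression at ingest keys on (datatype, timestamp, full
  payload), so overlapping weekly re-uploads are idempotent.
* The heat map of a single point is a 1×1 grid; ties in the modal home cell
  resolve to the first cell in scan order (deterministic).

## Problem sizes in the test suite

The suite verifies oracle equivalence (grid coding vs direct per-hour
scanning) on 200 randomized simulated days, noiseless ground-truth recovery
on 50 seeded days plus 25 days at 40% outage, and mobility metrics against
naive recomputation on 15 random days; the full run takes under a minute on
one CPU. These sizes are the package's chosen regression conditions; the
generators accept any scale.

## Limitations

The hour-coding rules are deliberately coarse (at-least-one-reading): they
surface rhythms for discussion in a counseling session and are not validated
clinical measures. Proximity conflates beacon range (5–50 m line of sight)
with togetherness; speech presence is environment-level, not mother-directed
speech; and the mobility features assume a single stable home. The package
processes one participant's local clock and does not handle daylight-saving
transitions within a day.
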