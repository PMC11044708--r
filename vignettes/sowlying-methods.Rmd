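---
title: "Methods: from leg-worn accelerometer to sow lying behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from leg-worn accelerometer to sow lying behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sowlying)
```

## The measurement model

A data logger strapped to a sow's hind leg records triaxial acceleration
at 1 Hz. Only the y-axis — the axis parallel to the leg — carries the
postural signal: in a standing sow the leg is roughly perpendicular to
the ground, so the y-axis reads close to 1 g of gravitational
acceleration; when she lies, the tarsus is roughly parallel to the
ground and the reading drops toward 0 g. Sitting places the hind leg in
the same orientation as lying, which is why a hind-leg sensor
fundamentally cannot separate the two — a fact that drives the
validation design below.

The classifier is a smoothed threshold:

$$\text{lying}_t \iff \operatorname{med}_{w}(|y|)_t < y^\*$$

with window $w = 32$ samples and critical lying value $y^\* = 0.75$ g by
default. The threshold is intentionally strict (well above the midpoint
of 0.5 g) because sows often rest the leg at an angle rather than flat.
The absolute value makes an inverted logger mounting (y near −1 g when
standing) harmless. Maximal lying runs become half-open bouts
$[\text{start}, \text{stop})$; half-open intervals make durations
additive and adjacency unambiguous.

### Why a median, and what exactly it computes

Brief struggles, steps and piglet contact produce spikes in either
direction; a moving median removes them without blurring genuine
transitions the way a mean would. Two design points were genuinely open
and are settled as follows:

* **What is smoothed.** By default the median filter is applied to the
  $|y|$ *signal* before thresholding (`smooth = "signal"`). The
  alternative — threshold first, then majority-vote the 0/1 labels — is
  available as `smooth = "binary"`. The two differ only at exact voting
  ties (16 of 32 samples low): the signal median is then 0.5 g, which is
  below the 0.75 g threshold (lying), while the binary vote resolves
  ties to upright.
* **Window placement.** The window is centred by default (`align =
  "center"`); a trailing window is available for strictly causal,
  online-style processing. An even window of 32 cannot be symmetric: it
  covers 16 samples behind and 15 ahead, and the median of an even count
  is the mean of the two central order statistics. At segment edges the
  centred window shrinks symmetrically to the largest balanced window
  around the sample. These conventions are fixed and the compiled filter
  is tested position-by-position against a brute-force quadratic-time
  median.

The centred 32-sample window means every transition is located to within
half a window, i.e. ±16 s at 1 Hz; that bound reappears in the recovery
tests.

### Coverage gaps

Loggers fail, get swapped, and produce corrupt rows. Any inter-sample
interval above `gap_tolerance` (default 5 s at 1 Hz) splits the trace
into segments. Smoothing and bout extraction never cross a gap, bouts
abutting a gap are flagged truncated, and gap time is excluded from all
duration denominators. Nothing is imputed — faulty stretches are simply
not evidence.

## Parturition-aligned summaries

Day 0 is the *calendar day* of parturition (wall-clock dates, not 24-h
offsets from the farrowing timestamp), and each day splits into four
6-h wall-clock quarters: late night 00–06, morning 06–12, afternoon
12–18, early night 18–24. The clock bounds of the quarters are a
configuration choice (`quarter_hours`); the default follows the
convention that "early night" is the 18:00–24:00 block in which lactating
sows lie almost continuously. Per quarter the summary reports the bout
count (each bout counted once, in the quarter containing its start — so
a bout spanning midnight is never double-counted), lying seconds as the
summed intersection of bouts with the quarter window, coverage seconds,
and the lying proportion. Two exactness invariants are enforced by test:
quarter lying seconds sum to daily lying seconds, and total bout duration
equals the lying-sample count divided by the sampling rate, segment by
segment.

## Validation against video

Video observers code lying and sitting as separate behaviours; the
sensor sees one "leg horizontal" state. Comparing the two naively
punishes the sensor for every transitional sit. The reconciliation rule
treats rest as the unit: every maximal chain of contiguous lying/sitting
events (gaps up to `adjacency_tolerance`, default 1 s — one sample at
1 Hz, tolerating sub-second slivers left by video coding) that contains
at least one lying event becomes a single *rest bout*; sitting chains
with no lying remain upright. This covers all three transitional cases:
sitting between lying bouts, before standing up, and before lying down.

Agreement is quantified on a subjects × methods matrix (one row per
sow × 24-h period) with a single-measure two-way random-effects
intraclass correlation. The ICC form matters and is often left implicit
in the literature; here it is explicit: the default is McGraw–Wong
ICC(A,1) — absolute agreement, since the question is whether the sensor
reproduces the video *values*, not merely their ranking — with the
consistency form ICC(C,1) available by flag. Mean squares are computed
from definitional sums of squares; confidence intervals use the standard
F-based interval with Satterthwaite degrees of freedom for the agreement
form. A constant matrix has no defined ICC and raises a classed error
rather than returning a number. Windows with zero sensor coverage are
dropped (mirroring exclusion of faulty records); partially covered
windows are retained down to a configurable coverage fraction (default
75%, accommodating partial observation days).

## What the simulator does and does not emulate

The simulator exists so that classification, merging, summarisation and
agreement are all testable at desk scale with known ground truth.

**Behaviour.** Rest/upright alternation is a two-state renewal process.
Each day-quarter has a target rest proportion $p$ and rest-bout rate $r$
(bouts per 6 h); episode-duration means are solved from them as
$\mu_{rest} = p \cdot 21600 / r$ and $\mu_{up} = (1-p) \cdot 21600 / r$.
Durations are shifted-exponential with a 60 s floor — the field's usual
minimum-bout criterion, and a guarantee that no episode is shorter than
the classifier's ±16 s boundary uncertainty; the floor is a parameter
(`min_episode_s`). The state carries continuously across quarter
boundaries (durations are redrawn when the regime changes), so a sow
lying at 05:59 is still lying at 06:00, and a full-day proportion-1
target yields a single 24-h rest bout. Episode boundaries are rounded to
whole seconds to stay on the 1 Hz grid. Rest episodes are then decorated
with transitional sitting: with configurable probability each rest
episode gains a sit before lying down, a sit before standing up, and one
interior sitting interruption (durations Gaussian, default 40 ± 20 s,
shed when they do not fit). The undecorated rest episodes are the ground
truth; merging the decorated ethogram's sitting must reconstruct them
exactly, and does, by test.

**Sensor.** Per posture episode one leg angle from vertical is drawn
(standing 5° ± 3°, lying/sitting 85° ± 3° by default), each sample reads
$\cos(\text{angle})$ g plus Gaussian noise (default sd 0.05 g), and a
burst of extra noise (default 5 s, sd 0.3 g) surrounds every posture
change, emulating the movement of actually lying down or getting up.

**Presets.** `preset("crate_default")` and `preset("free_default")`
encode the qualitative day-courses of the two housing systems over days
−3 to 27 as piecewise-linear interpolations: in crates, bout rate rises
toward parturition (peaking around five bouts per 6 h), collapses to
near zero right after it, and recovers moderately; in free-farrowing
pens it starts high, bottoms out after parturition, and climbs to about
eight bouts per 6 h by day 20 (nest-leaving); in both, the early-night
quarter is ≥ 95% lying on every day. These presets are scenario
fixtures for testing direction and magnitude of pipeline behaviour, not
empirical reproductions — no figure-derived numbers are asserted as
ground truth.

**What is not emulated.** Real traces contain lateral-vs-sternal
posture differences, nursing bouts, piglet interference, sensor drift,
slow postural shifts, and duration distributions that are certainly not
exponential. Passing tests on simulated data therefore demonstrate the
*internal* correctness of the chain (classification recovers the
simulated truth; merging reconstructs rest; ICC computes the right
statistic), not field accuracy of the 0.75 g threshold itself, which
only validation against real video can establish.

## Numerical and scale choices

* Timestamps are timezone-naive barn-local wall-clock times, stored as
  UTC-represented POSIXct so arithmetic never crosses a DST boundary;
  quarter boundaries are wall-clock by construction.
* Ties at exactly the critical value are upright (`<`, not `<=`).
* The even-window median convention (mean of the two central order
  statistics; 16 back / 15 ahead) is fixed and documented; re-running
  the classifier on its own idealized 0/1 output can shift transitions
  by at most one sample, which the tests bound explicitly.
* Degenerate inputs fail loudly: empty traces, overlapping ethogram
  events, constant ratings matrices, unreachable simulator targets
  (rate 0 with fractional proportion, or means below the episode floor)
  are all errors, not silent defaults.
* Test and validation problem sizes are chosen for a laptop-class
  single-core budget: Monte-Carlo checks of the renewal targets use
  1000 simulated days at the episode level; end-to-end recovery runs a
  few days of 1 Hz signal (10⁵–10⁶ samples); the agreement study uses
  23 sow-day subjects; oracle equivalence for the median filter uses
  100 random traces up to 10⁴ samples and for the ICC up to 50 × 4
  matrices.

## Known limitations

* The classifier detects *lying* only; sitting, sternal vs lateral
  posture, and multi-sensor fusion are out of scope.
* Bout-boundary resolution is limited to half the median window (±16 s
  at defaults); shortening the window trades artefact rejection for
  resolution.
* The ICC confidence interval for the agreement form relies on the
  Satterthwaite approximation, which is poorly behaved when the ratings
  matrix is nearly degenerate (the interval is then wide or collapses);
  the estimate itself is unaffected.
* Downstream inference on the quarter summaries (mixed models, spline
  day-courses, housing contrasts) is deliberately out of scope; the
  summary table is the hand-off point.
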