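---
title: "Engine design and simulation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Engine design and simulation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazejoint)
library(dplyr)
```

## The measurement problem

Joint attention (JA) — sharing attentional focus with a partner — is usually
measured in children with passive eye-tracking stimuli. A gaze-contingent
battery instead makes the on-screen partner *responsive*: her behavior
advances only when the participant produces the expected gaze behavior, so
responding to joint attention (RJA) and initiating joint attention (IJA, to
request or to comment/reference) can be operationalised as gaze events that
the participant must actively produce. gazejoint implements the logic of
such a battery as open, hardware-independent code: declarative trial
definitions, a trigger state machine, counterbalanced scheduling, outcome
scoring, and a simulator that stands in for the participant and the eye
tracker.

The engine deliberately models stimulus *timelines*, not pixels: a "phase"
is a segment of scripted video with a duration and (possibly) a gaze
trigger, and the engine's job is to decide when and why each phase ended.

## Coordinates, fixations, and the offset convention

All positions are screen pixels with the origin at the top-left corner and
y increasing downward; time is milliseconds on a session clock starting at
0. ROIs are half-open rectangles (`x0 <= x < x1`, `y0 <= y < y1`) so that
abutting regions partition their seam. A fixation belongs to the ROI
containing its *centroid*; this matches the trigger semantics of "a single
fixation on a target ROI" and keeps labeling a pure function of the
centroid and the ROI set.

Raw samples are parsed into fixations with the dispersion-threshold
algorithm (I-DT), the standard deterministic choice for screen-based data:
a fixation is a maximal run of valid samples whose dispersion
`(max x - min x) + (max y - min y)` stays within `max_dispersion_px`,
bridging invalid gaps up to `max_gap_ms` and requiring `min_duration_ms`.
Defaults are 60 px (about 1.5 degrees at a typical 60 cm viewing distance
on a 1920x1080 display), 60 ms, and 75 ms — conventional eye-movement
values, all below the engine's smallest trigger threshold (100 ms) so that
detection never masks a trigger. Deployed systems often use a vendor's
event parser instead; `as_fixations()` ingests such pre-detected event
tables directly, and the detector settings are exposed wherever detection
runs.

One convention matters for exact timing: each sample represents one
sampling interval of gaze, so a fixation's offset extends one interval past
its last sample. A stationary 300 ms burst at 300 Hz (90 samples) is
therefore detected with duration exactly 300 ms, and behavioral sweeps of
scripted fixations recover trigger thresholds exactly rather than one
sample short.

Because dispersion can only grow as a window extends, the greedy window
scan is provably identical to exhaustively testing all maximal windows
against the predicates; the test suite still checks this equivalence
against an independent brute-force oracle on randomised streams.

## Triggers and the phase state machine

Three scripted trigger thresholds define the battery's contingencies:

* attention-getter: a single fixation of at least **100 ms** on the
  attention-getter ROI, with no timeframe;
* initial looking-down phase: a single continuous fixation of at least
  **200 ms** on the partner's Face ROI within a **4 s** timeframe;
* IJA phases: a single uninterrupted gaze alternation — a Face fixation
  immediately followed by a Target (tablet or object) fixation — within a
  **7 s** timeframe.

A fixation trigger fires at `max(fixation onset, phase onset) +
threshold`; a fixation straddling the phase onset contributes only its
within-phase portion, so gaze already resting on the face cannot fire a
phase instantly. The 200 ms requirement is read as a single continuous
fixation, not cumulative dwell. The alternation is evaluated as a
two-state automaton over the fixation label sequence: Face arms it, an
immediately following Target completes it (firing at that fixation's
offset), any fixation outside the pair — including fixations that land on
no ROI — resets it without ending the phase, and re-fixations within the
same ROI preserve the state. The scripted order is Face then Target, since
the construct is directing the partner's attention *from* mutual gaze; an
`either_order` switch exists for sensitivity analyses. No duration
threshold beyond the detector's minimum applies to the fixations inside a
pair.

Each executed phase produces exactly one transition record with one cause:
`gaze_fixation`, `gaze_alternation`, `timeout`, or `override`. Timeouts
keep the battery moving when the expected behavior never occurs;
researcher-issued overrides handle technical failures such as calibration
drift, and each override command advances exactly one phase. At identical
timestamps precedence is override > gaze > timeout, which preserves
researcher control and credits the participant at timeframe boundaries.
Non-contingent phases end by a *scheduled* timeout (`scheduled = TRUE`),
distinguishing a scripted advance from an expired timeframe. Scoring later
uses these causes to separate participant-driven data from system- or
researcher-driven advances.

Two open design points were resolved as follows. A contingent IJA phase
that times out proceeds along the scripted chain to the response phase
(the partner responds anyway, with the trial's counterbalanced side), and
the `timeout` cause excludes it from success counts — the alternative,
skipping the response, would desynchronise the scripted video timeline.
And the attention-getter's unlimited wait is legal only there; in offline
replay, a never-fired attention-getter ends at the end of the available
data with a scheduled-timeout record, since a finite recording cannot wait
forever, while any other phase without trigger, finite duration, or
override raises an unbounded-wait error.

## The battery

The scripted timing per task (attention-getter excluded) is:

| task | phases (ms) | maximum |
|---|---|---|
| RJA | 4000 (Face trigger), 1500, 4000 (cue window) | 9.5 s |
| IJA-Request | 4000, 1500, 7000 (alternation), 3500, 10000 | 26 s |
| IJA-Comment/Reference | 4000, 7000 (alternation), 3000 | 14 s |
| greeting | 10000 | 10 s |
| training | 26000 (demonstration) + request chain | 52 s |

`build_battery()` constructs 32 scored stimuli — 16 RJA (two cues
x two directions x four object pairs), 8 IJA-Request (four video pairs,
each left/right), 8 IJA-Comment (four moving objects, each left/right) —
in four blocks of 4 + 2 + 2, directions balanced overall, per task, and
per block, preceded by a greeting and an unscored training trial. Summed
over the scored trials the maximum is 472 s, which rounds to 8 minutes
(about 2 per block). "Interleaved" presentation is under-specified in the
source design, so it is implemented as a seeded constrained shuffle within
each block that forbids three consecutive same-task stimuli; the seed only
permutes order — the trial multiset is provably identical across seeds,
and `validate_battery()` re-checks every counterbalancing invariant.

The training trial's internal split is not published beyond its 52 s cap;
it is modeled as a 26 s demonstration phase (the partner plays each tablet
video in turn) followed by the standard 26 s request chain, so its
unresponsive maximum equals the cap exactly.

No ROI coordinates are published either, so the layout ships as a
configurable template in screen fractions: face in the upper center,
targets/tablets on the table left and right, comment objects in the top
corners, and the 200x200 px attention-getter centered 15% of the screen in
from the bottom corner on the trial's side — inset because gaze estimation
degrades near screen edges, and placed at the bottom so no two ROIs of a
trial overlap (centroid labeling requires disjoint regions).

## Scoring

RJA follows "a first fixation on the target ROI from the face ROI at cue
onset": the participant must be fixating the Face when the cue starts
(otherwise the outcome is `none`, conservatively retained rather than
discarded), and the first subsequent fixation whose label leaves the Face
decides — cued target `correct`, opposite target `incorrect`, anything
else (another ROI, or no ROI) `none`, since the bid was not followed
first. Latency is that fixation's onset minus cue onset. IJA success is
simply whether the construct phase ended by a gaze-alternation cause, with
latency equal to the transition's latency ("time until successful gaze
alternating ended", measured from construct-phase onset). Construct phases
ended by override are excluded from analysis (`valid_for_analysis =
FALSE`); rates in `summarize_session()` are computed over valid trials
only, and a construct with zero valid trials reports an undefined (`NA`)
rate rather than 0. Saccades landing between ROIs are invisible to
scoring: the analysis is fixation-level throughout.

## The simulator

`simulate_session()` co-simulates a parameterised participant against the
engine itself: per phase, the model decides compliance (probabilities
`p_initiate`, `p_rja`, `p_request`, `p_comment`) and draws a response
latency from a lognormal distribution (natural-scale mean 600 ms, sd
200 ms by default — a realistic saccadic/decision latency for young
children — truncated so that an intended compliance completes within the
phase timeframe). Compliant behavior lays down the required fixation
events at ROI centers; non-compliance is wandering fixations over
non-trigger screen locations, so timeouts arise from *behavior*, with
per-sample dropout as a separate knob. Saccade transits are fixed at
30 ms and the default sampling rate is 300 Hz. The attention-getter is
always fixated, as in deployment it is researcher-supported.

The raw stream is synthesised from the same events, with Gaussian
positional jitter and dropout applied per sample. With zero noise, the
replayed stream reproduces every co-simulated transition within one sample
period, and scored latencies match intended latencies within one sample
period plus the detector minimum — the closed-loop property the test
suite asserts. Note that jitter interacts with I-DT: the dispersion of a
long fixation grows with the sample count, so jitter beyond roughly a
tenth of `max_dispersion_px` begins to fragment fixations, exactly as
tracker noise does in real recordings.

The simulator emulates compliance, latency, noise and dropout, but not
smooth pursuit, the oculomotor main sequence, microsaccades, binocular
disparity, head movement, or drift-like slow error. Passing tests
therefore demonstrate that the *engine and scoring logic* are correct
under controlled input, not that any particular child population will
behave like the model.

## Problem sizes and numerical choices

Checks run at desk scale: detector-oracle equivalence on streams of at
most 1,000 samples; the alternation automaton against enumeration of all
label sequences up to length 4; cause exclusivity and latency bounds on
100 randomly parameterised simulated sessions; counterbalancing invariants
over 100 seeds; and compliance-probability recovery from 500 replicate
8-trial sessions at `p_request = 0.6`, which must land in the exact
binomial 95% interval. Clock comparisons use a 1e-6 ms slack for floating
sampling grids (300 Hz has a period of 10/3 ms); ties at a phase boundary
resolve by the stated precedence. Degenerate inputs are defined, not
errors: an empty stream detects zero fixations, an empty battery has zero
duration, and an empty session scores all failures with every contingent
phase timing out.

## Limitations

The engine models timelines, not rendered video, so display-latency and
stitching artifacts of a deployed system are out of scope, as are
eye-tracker drivers, calibration, and vendor binary formats (text formats
only, by design). Where the published design is silent — ROI geometry,
training-trial split, interleaving pattern, vendor fixation-parser
settings — the defaults above are explicit, configurable surrogates, and
analyses sensitive to them should vary them through the configuration
surface rather than rely on the defaults.
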