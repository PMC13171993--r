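# gazejoint

**gazejoint** is an open, hardware-independent R engine for gaze-contingent
joint-attention (JA) experiments of the kind used in screen-based
eye-tracking research with autistic children. In such a battery, the
on-screen communication partner is *responsive*: her video advances only
when the participant produces the expected gaze behavior, so the two core
JA constructs become directly measurable gaze events —

* **RJA** (responding to joint attention): following the partner's
  referential cue (gaze shift or head turn) to its target object, scored as
  a first fixation on the target ROI from the face ROI after cue onset;
* **IJA** (initiating joint attention), to **request** (protoimperative)
  or to **comment/reference** (protodeclarative): directing the partner's
  attention by a single uninterrupted gaze alternation, a fixation on the
  Face ROI immediately followed by a fixation on the Target ROI (a tablet
  showing a desired video, or a suddenly appearing object).

The package provides every layer needed to run, score, and test such a
battery without eye-tracking hardware:

* **ROI geometry and fixation detection** — half-open pixel rectangles,
  centroid labeling, and dispersion-threshold (I-DT) parsing of raw
  `t_ms,x_px,y_px,valid` streams (`detect_fixations()`), or ingestion of
  pre-detected fixation tables (`as_fixations()`);
* **the contingency engine** — fixation triggers (≥ 100 ms on the
  attention-getter, ≥ 200 ms on the face within 4 s), gaze-alternation
  triggers (within 7 s, resetting on any interruption), contingency
  timeouts, and manual overrides, with one cause-tagged transition record
  per executed phase (`run_phase()`, `run_trial()`, `run_session()`);
* **the counterbalanced battery** — 32 scored stimuli (16 RJA, 8
  IJA-Request, 8 IJA-Comment/Reference) in four blocks of 4 + 2 + 2,
  directions balanced throughout, plus greeting (10 s) and training
  (max 52 s) trials (`build_battery()`, `validate_battery()`);
* **scoring** — per-trial outcomes and latencies that count only
  participant-driven triggers, with timeouts as failures and overrides
  excluded (`score_session()`, `summarize_session()`, `tidy()`,
  `glance()`, `autoplot()`);
* **a synthetic participant** — compliance probabilities, lognormal
  response latencies, positional jitter and dropout, co-simulated against
  the engine so every component is testable at desk scale
  (`participant_model()`, `simulate_session()`, `scripted_stream()`);
* **text-first IO and a CLI** — CSV gaze streams, JSON-lines transition
  logs, YAML battery/model configs with schema validation, a one-call
  pipeline (`run_pipeline()`), and a thin `exec/gazejoint` command line
  (`build`, `validate`, `simulate`, `run`).

## Worked example

Build the battery, simulate a moderately engaged participant, replay the
raw gaze stream through the engine, and score it:

```r
library(gazejoint)

b <- build_battery(seed = 42)
print(b)
#> <ja_battery> 32 scored stimuli in 4 blocks (seed 42)
#> # A tibble: 12 x 4
#>    block task        left right
#>  1     1 IJA_comment     1     1
#>  2     1 IJA_request     1     1
#>  3     1 RJA             2     2
#>  ...
#> max scored duration: 7.87 min

m <- participant_model(p_initiate = 0.9, p_rja = 0.7, p_request = 0.8,
                       p_comment = 0.6, jitter_px = 4, dropout_rate = 0.02,
                       seed = 42)
sim <- simulate_session(b, m)        # raw 300 Hz stream + ground truth
tr  <- run_session(b, samples = sim$stream)
res <- score_session(b, tr, detect_fixations(sim$stream))
tidy(summarize_session(res, tr))
#> # A tibble: 3 x 7
#>   task        n_trials n_valid n_success success_rate latency_mean_ms
#> 1 RJA               16      16        14        0.875            599.
#> 2 IJA_request        8       8         6        0.75             734.
#> 3 IJA_comment        8       8         3        0.375            820
```

The scored rates track the model's compliance probabilities (0.7 / 0.8 /
0.6) up to binomial noise at n = 16 / 8 / 8; `success_rate` is computed
over analysable trials only (overridden construct phases are excluded),
and latencies are means over successful trials, in ms from construct-phase
onset. `plot_session_timeline(tr)` shows each phase colored by the cause
that ended it, and `plot_gaze(sim$stream, b$spec[[3]]$rois)` overlays the
stream on a trial's ROI layout.

The same pipeline runs from the shell:

```sh
exec/gazejoint build --seed 42 --out battery.yaml
exec/gazejoint simulate --config battery.yaml --seed 42 --out out/
```

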