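#' Gaze trigger specifications
#'
#' A trigger describes the participant gaze behavior that advances a
#' contingent phase. Two kinds exist:
#'
#' * **fixation** -- a single continuous fixation of at least
#'   `min_fixation_ms` on one ROI. The attention-getter uses a 100 ms
#'   threshold; the initial looking-down phase of every stimulus uses 200 ms
#'   on the Face ROI.
#' * **alternation** -- a single uninterrupted sequence of consecutive
#'   fixations from the partner's Face ROI to a Target ROI (tablet or
#'   suddenly-appearing object). Any intervening fixation outside the pair's
#'   ROIs resets the sequence while the stimulus continues to play;
#'   re-fixations within the same ROI do not count as interruptions.
#'
#' @param roi ROI id the fixation trigger watches.
#' @param min_fixation_ms Minimum continuous fixation duration, ms.
#' @param roi_face,roi_target ROI id pair for the alternation trigger
#'   (distinct).
#' @param either_order If `TRUE`, a Target-then-Face pair also fires
#'   (sensitivity-analysis switch; the default, `FALSE`, requires
#'   Face then Target).
#' @return A `ja_trigger` object.
#' @export
trigger_fixation <- function(roi, min_fixation_ms = 200) {
  stopifnot(is.character(roi), length(roi) == 1L, min_fixation_ms > 0)
  structure(list(kind = "fixation", roi = roi,
                 min_fixation_ms = as.numeric(min_fixation_ms)),
            class = "ja_trigger")
}

#' @rdname trigger_fixation
#' @export
trigger_alternation <- function(roi_face, roi_target, either_order = FALSE) {
  stopifnot(is.character(roi_face), is.character(roi_target))
  if (identical(roi_face, roi_target))
    abort("alternation trigger requires two distinct ROI ids")
  structure(list(kind = "alternation", roi_face = roi_face,
                 roi_target = roi_target, either_order = isTRUE(either_order)),
            class = "ja_trigger")
}

#' Declarative phase specification
#'
#' A phase is one segment of a stimulus timeline. Contingent phases carry
#' exactly one trigger and a finite `duration_ms` acting as the trigger
#' timeframe (or `NA` for an unlimited wait, allowed only for the
#' attention-getter); non-contingent phases have no trigger and advance by a
#' scheduled timeout at `duration_ms`. `on_trigger` / `on_timeout` name the
#' next phase index (NA = terminal).
#'
#' @param phase Integer phase index (attention-getter = 0).
#' @param duration_ms Fixed playback duration or trigger timeframe, ms
#'   (`NA` = unlimited).
#' @param trigger A [trigger_fixation()] / [trigger_alternation()], or `NULL`.
#' @param on_trigger,on_timeout Next phase index after a gaze/override
#'   trigger or a timeout.
#' @return One-row tibble with a list-column `trigger`.
#' @export
phase_spec <- function(phase, duration_ms = NA_real_, trigger = NULL,
                       on_trigger = NA_integer_, on_timeout = NA_integer_) {
  if (!is.null(trigger) && !inherits(trigger, "ja_trigger"))
    abort("trigger must be a ja_trigger or NULL")
  if (!is.na(duration_ms) && duration_ms <= 0)
    abort("duration_ms must be positive when finite")
  tibble(phase = as.integer(phase), duration_ms = as.numeric(duration_ms),
         trigger = list(trigger), on_trigger = as.integer(on_trigger),
         on_timeout = as.integer(on_timeout))
}

#' Evaluate a fixation trigger against a fixation stream
#'
#' Fires at the earliest instant a single fixation labeled with the
#' trigger's ROI has accumulated `min_fixation_ms` of dwell inside the phase
#' window: `fire_time = max(fixation onset, phase_onset) + min_fixation_ms`.
#' A fixation straddling the phase onset contributes only its within-phase
#' portion, so pre-phase gaze cannot fire instantly. Fixations shorter than
#' the threshold, outside the ROI, or whose fire time exceeds `phase_end`
#' never fire.
#'
#' @param fixations Labeled, time-ordered fixation tibble (see
#'   [label_fixations()]).
#' @param trigger A `ja_trigger` of the matching kind.
#' @param phase_onset Phase start on the session clock, ms.
#' @param phase_end Absolute end of the trigger timeframe, ms (`Inf` =
#'   unlimited).
#' @return List with `fired` (logical) and `fire_time` (ms or `NA`).
#' @export
eval_fixation_trigger <- function(fixations, trigger, phase_onset = 0,
                                  phase_end = Inf) {
  stopifnot(inherits(trigger, "ja_trigger"), trigger$kind == "fixation")
  lab <- fixations$roi
  cand <- !is.na(lab) & lab == trigger$roi &
    fixations$offset_ms > phase_onset + .ja_eps &
    fixations$onset_ms < phase_end
  if (any(cand)) {
    on <- pmax(fixations$onset_ms[cand], phase_onset)
    fire <- on + trigger$min_fixation_ms
    ok <- fire <= fixations$offset_ms[cand] + .ja_eps & fire <= phase_end + .ja_eps
    if (any(ok)) {
      return(list(fired = TRUE, fire_time = min(fire[ok])))
    }
  }
  list(fired = FALSE, fire_time = NA_real_)
}

#' Evaluate a gaze-alternation trigger against a fixation stream
#'
#' Scans the label sequence of fixations overlapping the phase window with a
#' two-state automaton: seeing the Face ROI arms the sequence; an
#' immediately following Target fixation completes it and the trigger fires
#' at that fixation's offset; any fixation labeled outside the pair
#' (including unlabeled fixations between ROIs) resets the sequence without
#' ending the phase; repeated fixations within the same ROI keep the state.
#' The completing fixation must begin inside the phase and end within
#' `phase_end`.
#'
#' @inheritParams eval_fixation_trigger
#' @return List with `fired` and `fire_time`.
#' @export
eval_alternation_trigger <- function(fixations, trigger, phase_onset = 0,
                                     phase_end = Inf) {
  stopifnot(inherits(trigger, "ja_trigger"), trigger$kind == "alternation")
  keep <- fixations$offset_ms > phase_onset + .ja_eps &
    fixations$onset_ms < phase_end
  f <- fixations[keep, , drop = FALSE]
  if (nrow(f) == 0L) return(list(fired = FALSE, fire_time = NA_real_))
  f <- f[order(f$onset_ms), , drop = FALSE]
  lab <- ifelse(is.na(f$roi), "", f$roi)
  prev <- ""
  for (k in seq_along(lab)) {
    completes <-
      (prev == trigger$roi_face && lab[k] == trigger$roi_target) ||
      (trigger$either_order &&
         prev == trigger$roi_target && lab[k] == trigger$roi_face)
    if (completes &&
        f$onset_ms[k] >= phase_onset - .ja_eps &&
        f$offset_ms[k] <= phase_end + .ja_eps) {
      return(list(fired = TRUE, fire_time = f$offset_ms[k]))
    }
    prev <- if (lab[k] %in% c(trigger$roi_face, trigger$roi_target)) lab[k] else ""
  }
  list(fired = FALSE, fire_time = NA_real_)
}

.consume_override <- function(overrides, t_fired) {
  i <- which(abs(overrides$t_ms - t_fired) <= .ja_eps)
  if (length(i)) overrides <- overrides[-i[1L], , drop = FALSE]
  overrides
}

eval_trigger <- function(fixations, trigger, phase_onset, phase_end) {
  switch(trigger$kind,
    fixation = eval_fixation_trigger(fixations, trigger, phase_onset, phase_end),
    alternation = eval_alternation_trigger(fixations, trigger, phase_onset, phase_end),
    abort(paste0("unknown trigger kind: ", trigger$kind))
  )
}

#' Execute one phase of a stimulus
#'
#' Resolves the single transition ending a phase: the earliest event among a
#' manual override, a gaze trigger, and the timeout at
#' `phase_onset + duration_ms`. At identical timestamps precedence is
#' override > gaze > timeout, preserving researcher control and favoring
#' participant-driven data at timeframe boundaries. Non-contingent phases
#' always end by a scheduled timeout at `duration_ms` (recorded with
#' `scheduled = TRUE` so scorers can tell a scripted advance from an expired
#' timeframe).
#'
#' A phase with an unlimited wait (`duration_ms = NA`) is only legal when it
#' has a trigger and `allow_unbounded = TRUE` (the attention-getter); in
#' offline replay such a phase advances at the end of the available data
#' (`data_end`) when its trigger never fires.
#'
#' @param phase One-row phase tibble from [phase_spec()].
#' @param fixations Labeled fixation tibble.
#' @param overrides Tibble with columns `t_ms` (and optionally `note`), or
#'   `NULL`.
#' @param phase_onset Phase start, ms.
#' @param trial_id Trial identifier copied into the record.
#' @param allow_unbounded Permit an unlimited wait for this phase.
#' @param data_end End of the replayed data on the session clock, ms.
#' @return One-row transition tibble: `trial_id`, `phase`, `cause`
#'   (`gaze_fixation`, `gaze_alternation`, `timeout`, `override`), `t_ms`,
#'   `latency_ms`, `scheduled`.
#' @export
run_phase <- function(phase, fixations, overrides = NULL, phase_onset = 0,
                      trial_id = NA_character_, allow_unbounded = FALSE,
                      data_end = NULL) {
  if (is.data.frame(phase)) {
    trig <- phase$trigger[[1L]]
    dur <- phase$duration_ms[1L]
    idx <- phase$phase[1L]
  } else {
    trig <- phase$trigger; dur <- phase$duration_ms; idx <- phase$phase
  }
  timeout_t <- if (is.na(dur)) Inf else phase_onset + dur

  ov_t <- Inf
  if (!is.null(overrides) && nrow(overrides) > 0L) {
    in_win <- overrides$t_ms >= phase_onset - .ja_eps &
      overrides$t_ms <= timeout_t + .ja_eps
    if (any(in_win)) ov_t <- min(overrides$t_ms[in_win])
  }

  gz_t <- Inf; gz_cause <- NA_character_
  if (!is.null(trig)) {
    hit <- eval_trigger(fixations, trig, phase_onset, timeout_t)
    if (hit$fired) {
      gz_t <- hit$fire_time
      gz_cause <- if (trig$kind == "fixation") "gaze_fixation" else "gaze_alternation"
    }
  }

  # precedence at equal timestamps: override > gaze > timeout
  if (is.finite(ov_t) && ov_t <= gz_t + .ja_eps && ov_t <= timeout_t + .ja_eps) {
    t_end <- ov_t; cause <- "override"; scheduled <- FALSE
  } else if (is.finite(gz_t) && gz_t <= timeout_t + .ja_eps) {
    t_end <- gz_t; cause <- gz_cause; scheduled <- FALSE
  } else if (is.finite(timeout_t)) {
    t_end <- timeout_t; cause <- "timeout"; scheduled <- is.null(trig)
  } else if (allow_unbounded && !is.null(trig)) {
    # unlimited wait, data exhausted: advance at the end of the replayed data
    t_end <- max(phase_onset, data_end %||% phase_onset)
    cause <- "timeout"; scheduled <- TRUE
  } else {
    abort(paste0("phase ", idx, " would wait forever: no trigger fired, no ",
                 "finite duration, and no override supplied"))
  }

  tibble(trial_id = trial_id, phase = as.integer(idx), cause = cause,
         t_ms = t_end, latency_ms = t_end - phase_onset, scheduled = scheduled)
}

#' Run one trial through the contingency engine
#'
#' Executes a trial's phase chain from the attention-getter to the terminal
#' phase, following `on_trigger` / `on_timeout` edges, and returns one
#' transition record per executed phase. Accepts raw samples (detected with
#' [detect_fixations()]), an unlabeled fixation table (labeled against the
#' trial's ROIs), or pre-labeled fixations.
#'
#' @param trial A `ja_trial` from [make_trial()].
#' @param fixations Fixation tibble (labeled or not), or `NULL` when
#'   `samples` is given.
#' @param samples Raw gaze stream, alternative to `fixations`.
#' @param overrides Manual override tibble (`t_ms`, `note`) or `NULL`.
#' @param t0 Trial start on the session clock, ms.
#' @param max_dispersion_px,min_duration_ms,max_gap_ms Detector settings used
#'   when `samples` is given (see [detect_fixations()]).
#' @return Transition tibble, one row per executed phase.
#' @export
run_trial <- function(trial, fixations = NULL, samples = NULL, overrides = NULL,
                      t0 = 0, max_dispersion_px = 60, min_duration_ms = 60,
                      max_gap_ms = 75) {
  stopifnot(inherits(trial, "ja_trial"))
  if (is.null(fixations)) {
    if (is.null(samples)) {
      fixations <- tibble(onset_ms = numeric(), offset_ms = numeric(),
                          cx_px = numeric(), cy_px = numeric(),
                          duration_ms = numeric())
    } else {
      fixations <- detect_fixations(samples, max_dispersion_px,
                                    min_duration_ms, max_gap_ms)
    }
  } else {
    fixations <- as_fixations(fixations)
  }
  if (!"roi" %in% names(fixations))
    fixations <- label_fixations(fixations, trial$rois)

  data_end <- max(c(t0, fixations$offset_ms,
                    if (!is.null(overrides)) overrides$t_ms))
  ph <- trial$phases
  recs <- list()
  cur <- ph$phase[1L]
  onset <- t0
  while (!is.na(cur)) {
    row <- ph[ph$phase == cur, , drop = FALSE]
    if (nrow(row) != 1L) abort(paste0("trial ", trial$trial_id,
                                      ": unknown phase index ", cur))
    rec <- run_phase(row, fixations, overrides, phase_onset = onset,
                     trial_id = trial$trial_id,
                     allow_unbounded = is.na(row$duration_ms[1L]),
                     data_end = data_end)
    recs[[length(recs) + 1L]] <- rec
    # one override command advances exactly one phase
    if (rec$cause == "override") overrides <- .consume_override(overrides, rec$t_ms)
    onset <- rec$t_ms
    cur <- if (rec$cause == "timeout") row$on_timeout[1L] else row$on_trigger[1L]
  }
  bind_rows(recs)
}

#' Run a whole session through the contingency engine
#'
#' Replays a gaze record against every trial of a battery in presentation
#' order. Each trial starts on the session clock where the previous trial
#' ended; overrides are matched by time.
#'
#' @param battery A `ja_battery` from [build_battery()].
#' @param samples Raw gaze stream covering the session, or `NULL`.
#' @param fixations Pre-detected (optionally pre-labeled) fixations,
#'   alternative to `samples`.
#' @param overrides Manual override tibble or `NULL`.
#' @param t0 Session clock at the start of the first trial, ms.
#' @inheritParams run_trial
#' @return Transition tibble over all trials.
#' @export
run_session <- function(battery, samples = NULL, fixations = NULL,
                        overrides = NULL, t0 = 0, max_dispersion_px = 60,
                        min_duration_ms = 60, max_gap_ms = 75) {
  stopifnot(inherits(battery, "ja_battery"))
  if (is.null(fixations) && !is.null(samples)) {
    fixations <- detect_fixations(samples, max_dispersion_px,
                                  min_duration_ms, max_gap_ms)
  }
  if (is.null(fixations)) {
    fixations <- tibble(onset_ms = numeric(), offset_ms = numeric(),
                        cx_px = numeric(), cy_px = numeric(),
                        duration_ms = numeric())
  }
  pre_labeled <- "roi" %in% names(fixations)
  out <- vector("list", nrow(battery))
  t <- t0
  for (i in seq_len(nrow(battery))) {
    trial <- battery$spec[[i]]
    fx <- if (pre_labeled) fixations else label_fixations(fixations, trial$rois)
    tr <- run_trial(trial, fixations = fx, overrides = overrides, t0 = t)
    out[[i]] <- tr
    for (tt in tr$t_ms[tr$cause == "override"])
      overrides <- .consume_override(overrides, tt)
    t <- tr$t_ms[nrow(tr)]
  }
  bind_rows(out)
}
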