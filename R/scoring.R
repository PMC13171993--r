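#' Score a responding-to-joint-attention (RJA) trial
#'
#' The RJA outcome is a first fixation on a target ROI from the face ROI at
#' cue onset: within the 4 s cue window (phase 3), the participant must be
#' fixating the Face ROI at (or overlapping) cue onset; the first subsequent
#' fixation whose label leaves the Face then decides the outcome --
#' `correct` on the cued-side target, `incorrect` on the opposite target,
#' and `none` when gaze never leaves the face within the window, lands
#' outside both targets, or the participant was not on the face at cue
#' onset. Latency is that fixation's onset minus cue onset. A trial whose
#' cue phase ended by manual override is flagged `valid_for_analysis =
#' FALSE` so only participant-driven data enter the analysis.
#'
#' @param trial A `ja_trial` with `task == "RJA"`.
#' @param transitions The trial's transition records from [run_trial()].
#' @param fixations Labeled fixation tibble for the session.
#' @return One-row result tibble (see [score_session()]).
#' @export
score_rja <- function(trial, transitions, fixations) {
  stopifnot(inherits(trial, "ja_trial"), trial$task == "RJA")
  tr <- transitions[transitions$trial_id == trial$trial_id, , drop = FALSE]
  p3 <- tr[tr$phase == 3L, , drop = FALSE]
  if (nrow(p3) != 1L)
    abort(paste0("trial ", trial$trial_id, ": missing phase-3 transition record"))
  if (!"roi" %in% names(fixations))
    fixations <- label_fixations(fixations, trial$rois)

  cue_onset <- p3$t_ms - p3$latency_ms
  win_end <- cue_onset + 4000
  cued <- if (trial$direction == "left") "TargetLeft" else "TargetRight"
  other <- if (trial$direction == "left") "TargetRight" else "TargetLeft"

  outcome <- "none"; latency <- NA_real_
  on_face <- !is.na(fixations$roi) & fixations$roi == "Face" &
    fixations$onset_ms <= cue_onset + .ja_eps &
    fixations$offset_ms > cue_onset + .ja_eps
  if (any(on_face)) {
    after <- fixations[fixations$onset_ms > cue_onset &
                         fixations$onset_ms < win_end &
                         (is.na(fixations$roi) | fixations$roi != "Face"), ,
                       drop = FALSE]
    if (nrow(after) > 0L) {
      first <- after[which.min(after$onset_ms), ]
      if (!is.na(first$roi) && first$roi == cued) {
        outcome <- "correct"; latency <- first$onset_ms - cue_onset
      } else if (!is.na(first$roi) && first$roi == other) {
        outcome <- "incorrect"; latency <- first$onset_ms - cue_onset
      }
    }
  }

  .ja_result_row(trial, tr,
                 rja_outcome = outcome, ija_success = NA,
                 latency_ms = latency,
                 valid_for_analysis = p3$cause != "override")
}

#' Score an initiating-joint-attention (IJA) trial
#'
#' An IJA trial succeeds iff its construct phase -- the 7 s alternation
#' window, phase 3 for request and phase 2 for comment/reference -- ended
#' with a gaze-alternation trigger; the latency is the total time from the
#' construct phase's onset until the successful alternation ended (the
#' transition's latency). A timeout is a failure with no latency; a manual
#' override excludes the trial from analysis.
#'
#' @param trial A `ja_trial` with task `"IJA_request"` or `"IJA_comment"`.
#' @param transitions The trial's transition records.
#' @return One-row result tibble (see [score_session()]).
#' @export
score_ija <- function(trial, transitions) {
  stopifnot(inherits(trial, "ja_trial"),
            trial$task %in% c("IJA_request", "IJA_comment"))
  tr <- transitions[transitions$trial_id == trial$trial_id, , drop = FALSE]
  construct <- if (trial$task == "IJA_request") 3L else 2L
  pc <- tr[tr$phase == construct, , drop = FALSE]
  if (nrow(pc) != 1L)
    abort(paste0("trial ", trial$trial_id, ": missing construct-phase record"))

  if (pc$cause == "gaze_alternation") {
    success <- TRUE; latency <- pc$latency_ms; valid <- TRUE
  } else if (pc$cause == "timeout") {
    success <- FALSE; latency <- NA_real_; valid <- TRUE
  } else {
    success <- NA; latency <- NA_real_; valid <- FALSE
  }
  .ja_result_row(trial, tr, rja_outcome = NA_character_,
                 ija_success = success, latency_ms = latency,
                 valid_for_analysis = valid)
}

.ja_result_row <- function(trial, tr, rja_outcome, ija_success, latency_ms,
                           valid_for_analysis) {
  p1 <- tr[tr$phase == 1L, , drop = FALSE]
  tibble(
    trial_id = trial$trial_id, task = trial$task, cue = trial$cue,
    direction = trial$direction,
    phase1_cause = if (nrow(p1)) p1$cause else NA_character_,
    rja_outcome = rja_outcome, ija_success = ija_success,
    latency_ms = latency_ms, valid_for_analysis = valid_for_analysis
  )
}

#' Score every scored trial of a session
#'
#' Applies [score_rja()] / [score_ija()] across the battery's scored trials
#' (the greeting and training introduction are never scored).
#'
#' @param battery A `ja_battery`.
#' @param transitions Session transition records from [run_session()].
#' @param fixations Fixation tibble (labeled per trial as needed).
#' @return A `ja_results` tibble, one row per scored trial: `trial_id`,
#'   `task`, `cue`, `direction`, `phase1_cause`, `rja_outcome`
#'   (`correct` / `incorrect` / `none`, `NA` for IJA), `ija_success`
#'   (logical, `NA` for RJA or overridden trials), `latency_ms`,
#'   `valid_for_analysis`.
#' @export
score_session <- function(battery, transitions, fixations = NULL) {
  stopifnot(inherits(battery, "ja_battery"))
  if (is.null(fixations)) {
    fixations <- tibble(onset_ms = numeric(), offset_ms = numeric(),
                        cx_px = numeric(), cy_px = numeric(),
                        duration_ms = numeric())
  }
  pre_labeled <- "roi" %in% names(fixations)
  rows <- purrr::map(battery$spec[battery$scored], function(trial) {
    if (trial$task == "RJA") {
      fx <- if (pre_labeled) fixations else label_fixations(fixations, trial$rois)
      score_rja(trial, transitions, fx)
    } else {
      score_ija(trial, transitions)
    }
  })
  out <- bind_rows(rows)
  class(out) <- c("ja_results", class(out))
  out
}

#' Summarise a scored session by construct
#'
#' Aggregates per-trial results into construct-level rates and latency
#' statistics: the RJA correct rate and the IJA request/comment success
#' rates are computed over `valid_for_analysis` trials only (a construct
#' with zero valid trials reports an undefined, `NA`, rate -- not 0), and
#' latency statistics are computed over successful trials only. When the
#' transition log is supplied, a trigger-cause histogram per phase is
#' attached; its counts sum to the number of executed phases.
#'
#' @param results A `ja_results` tibble from [score_session()].
#' @param transitions Optional transition log for the cause histogram.
#' @return A `ja_session_summary` list with elements `by_construct`
#'   (tibble), `cause_histogram` (tibble or `NULL`) and `n_trials`.
#' @export
summarize_session <- function(results, transitions = NULL) {
  per_task <- function(tk) {
    r <- results[results$task == tk, , drop = FALSE]
    v <- r[r$valid_for_analysis, , drop = FALSE]
    hit <- if (tk == "RJA") {
      !is.na(v$rja_outcome) & v$rja_outcome == "correct"
    } else {
      !is.na(v$ija_success) & v$ija_success
    }
    lat <- v$latency_ms[hit]
    tibble(
      task = tk, n_trials = nrow(r), n_valid = nrow(v),
      n_success = sum(hit),
      success_rate = if (nrow(v) > 0L) sum(hit) / nrow(v) else NA_real_,
      latency_mean_ms = if (length(lat)) mean(lat, na.rm = TRUE) else NA_real_,
      latency_median_ms = if (length(lat)) median(lat, na.rm = TRUE) else NA_real_
    )
  }
  by_construct <- bind_rows(lapply(.ja_scored_tasks, per_task))
  hist <- NULL
  if (!is.null(transitions)) {
    hist <- transitions |>
      count(.data$phase, .data$cause, name = "n_transitions") |>
      arrange(.data$phase, .data$cause)
  }
  structure(list(by_construct = by_construct, cause_histogram = hist,
                 n_trials = nrow(results)),
            class = "ja_session_summary")
}

#' @export
print.ja_session_summary <- function(x, ...) {
  cat("<ja_session_summary> ", x$n_trials, " scored trials\n", sep = "")
  print(x$by_construct)
  if (!is.null(x$cause_histogram)) {
    cat("trigger-cause histogram:\n")
    print(x$cause_histogram)
  }
  invisible(x)
}

#' Tidy a session summary
#'
#' @param x A `ja_session_summary`.
#' @param ... Unused.
#' @return The per-construct tibble (`tidy`) or a one-row session overview
#'   (`glance`).
#' @export
tidy.ja_session_summary <- function(x, ...) x$by_construct

#' @rdname tidy.ja_session_summary
#' @export
glance.ja_session_summary <- function(x, ...) {
  bc <- x$by_construct
  tibble(
    n_trials = x$n_trials,
    n_valid = sum(bc$n_valid),
    rja_rate = bc$success_rate[bc$task == "RJA"],
    ija_request_rate = bc$success_rate[bc$task == "IJA_request"],
    ija_comment_rate = bc$success_rate[bc$task == "IJA_comment"]
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
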