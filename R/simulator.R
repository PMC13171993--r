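#' Parameterised synthetic participant
#'
#' Describes a simulated participant viewing the battery on a screen-based
#' eye tracker: per-construct compliance probabilities, a lognormal response
#' latency (positively skewed with positive support, the conventional shape
#' for saccadic/decision latencies; parameterised by its natural-scale mean
#' and sd and truncated at the phase timeframe so an intended compliance
#' always completes in time), Gaussian positional jitter, per-sample data
#' dropout, and the sampling rate. Non-compliance is modeled as wandering
#' fixations over non-trigger screen locations rather than track loss, so
#' timeouts arise from behavior; dropout is a separate knob. The
#' attention-getter is always fixated (in deployment it is researcher
#' supported and merely anchors the starting gaze position).
#'
#' @param p_initiate Probability of fixating the face during the initial
#'   looking-down phase.
#' @param p_rja Probability of correctly following the referential cue.
#' @param p_request,p_comment Probability of producing the request / comment
#'   gaze alternation.
#' @param latency_mean_ms,latency_sd_ms Natural-scale mean and sd of the
#'   lognormal response latency.
#' @param jitter_px Gaussian sd of fixation positional noise, px.
#' @param dropout_rate Per-sample probability of an invalid sample.
#' @param sampling_hz Sample rate of the emitted gaze stream.
#' @param seed Default RNG seed for [simulate_session()].
#' @return A `ja_participant` object.
#' @export
participant_model <- function(p_initiate = 1, p_rja = 1, p_request = 1,
                              p_comment = 1, latency_mean_ms = 600,
                              latency_sd_ms = 200, jitter_px = 0,
                              dropout_rate = 0, sampling_hz = 300, seed = 1L) {
  probs <- c(p_initiate, p_rja, p_request, p_comment)
  stopifnot(all(probs >= 0 & probs <= 1), sampling_hz > 0, jitter_px >= 0,
            dropout_rate >= 0, dropout_rate < 1,
            latency_mean_ms > 0, latency_sd_ms >= 0)
  structure(list(p_initiate = p_initiate, p_rja = p_rja,
                 p_request = p_request, p_comment = p_comment,
                 latency_mean_ms = latency_mean_ms,
                 latency_sd_ms = latency_sd_ms, jitter_px = jitter_px,
                 dropout_rate = dropout_rate, sampling_hz = sampling_hz,
                 seed = as.integer(seed)),
            class = "ja_participant")
}

#' @export
print.ja_participant <- function(x, ...) {
  cat("<ja_participant> p(initiate/rja/request/comment) = ",
      paste(c(x$p_initiate, x$p_rja, x$p_request, x$p_comment), collapse = "/"),
      ", latency ", x$latency_mean_ms, " +/- ", x$latency_sd_ms, " ms, ",
      x$sampling_hz, " Hz\n", sep = "")
  invisible(x)
}

# truncated lognormal latency draw (natural-scale mean/sd)
.sim_latency <- function(model, lo, hi) {
  if (model$latency_sd_ms == 0) return(min(max(model$latency_mean_ms, lo), hi))
  cv2 <- (model$latency_sd_ms / model$latency_mean_ms)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(model$latency_mean_ms) - sdlog^2 / 2
  min(max(rlnorm(1L, meanlog, sdlog), lo), hi)
}

# mutable event accumulator for one simulated session ---------------------

.sim_new_acc <- function() {
  env <- new.env(parent = emptyenv())
  env$roi <- character(); env$x <- env$y <- env$onset <- env$dur <- numeric()
  env$trial <- character(); env$phase <- integer()
  env
}

.sim_end <- function(acc) {
  n <- length(acc$onset)
  if (n == 0L) -Inf else acc$onset[n] + acc$dur[n]
}

.sim_add <- function(acc, trial_id, phase, roi, x, y, onset, dur) {
  onset <- max(onset, .sim_end(acc) + 30)
  if (dur < 60) return(invisible(NULL))  # below detectability, skip
  n <- length(acc$onset) + 1L
  acc$trial[n] <- trial_id; acc$phase[n] <- as.integer(phase)
  acc$roi[n] <- roi %||% NA_character_
  acc$x[n] <- x; acc$y[n] <- y; acc$onset[n] <- onset; acc$dur[n] <- dur
  invisible(NULL)
}

# dwell on a ROI until `until`: extend the last event when it is already on
# that ROI (a continued fixation), else open a new one after a saccade
.sim_dwell <- function(acc, trial_id, phase, roi, centers, until, from = 0) {
  n <- length(acc$onset)
  if (n > 0L && !is.na(acc$roi[n]) && acc$roi[n] == roi) {
    acc$dur[n] <- max(acc$dur[n], until - acc$onset[n])
    return(invisible(NULL))
  }
  p <- centers[centers$id == roi, ]
  if (nrow(p) != 1L)
    abort(paste0("simulator: ROI '", roi, "' not in the trial's ROI set"))
  start <- max(from, .sim_end(acc) + 30)
  .sim_add(acc, trial_id, phase, roi, p$x, p$y, start, until - start)
}

# non-compliant behavior: wandering fixations over non-trigger locations
.sim_wander <- function(acc, trial_id, phase, screen, from, to) {
  spots <- rbind(c(0.36, 0.925), c(0.50, 0.915), c(0.65, 0.925))
  k <- 0L
  t <- max(from, .sim_end(acc) + 30)
  while (to - t >= 90) {
    d <- min(470, to - t)
    s <- spots[k %% 3L + 1L, ]
    .sim_add(acc, trial_id, phase, NA_character_, s[1] * screen[1],
             s[2] * screen[2], t, d)
    t <- .sim_end(acc) + 30
    k <- k + 1L
  }
  invisible(NULL)
}

.sim_fixations <- function(acc) {
  tibble(onset_ms = acc$onset, offset_ms = acc$onset + acc$dur,
         cx_px = acc$x, cy_px = acc$y, duration_ms = acc$dur, roi = acc$roi)
}

#' Simulate a whole session against the contingency engine
#'
#' Co-simulates a participant viewing the battery: phase by phase, the
#' model decides whether the participant produces the required gaze behavior
#' and with what latency, intended fixation events are laid down, and the
#' engine's own [run_phase()] resolves each transition so later phases react
#' to earlier triggers exactly as in a live run. Returns the intended
#' ("ground truth") behavior per trial, the engine transition log, the
#' intended labeled fixations, and (optionally) a continuous raw gaze stream
#' at `sampling_hz` with jitter and dropout applied. With zero jitter and
#' dropout, every intended compliance produces the corresponding gaze-caused
#' transition when the stream is replayed through [detect_fixations()] and
#' [run_session()].
#'
#' @param battery A `ja_battery`.
#' @param model A [participant_model()].
#' @param seed RNG seed (defaults to the model's).
#' @param return_stream Also synthesise the raw sample stream (slower; the
#'   event-level fixation table is always returned).
#' @return List with `truth` (one row per trial: intended initiation and
#'   construct compliance, intended latency, side), `transitions`,
#'   `fixations` (intended, labeled) and `stream` (tibble or `NULL`).
#' @export
simulate_session <- function(battery, model, seed = model$seed,
                             return_stream = TRUE) {
  stopifnot(inherits(battery, "ja_battery"), inherits(model, "ja_participant"))
  screen <- attr(battery, "screen") %||% c(1920, 1080)
  withr::with_seed(as.integer(seed), {
    acc <- .sim_new_acc()
    truth <- vector("list", nrow(battery))
    trans <- vector("list", nrow(battery))
    t <- 0
    for (i in seq_len(nrow(battery))) {
      res <- .sim_trial(battery$spec[[i]], model, t, acc, screen)
      truth[[i]] <- res$truth
      trans[[i]] <- res$transitions
      t <- res$t_end
    }
    fixations <- .sim_fixations(acc)
    stream <- NULL
    if (return_stream) {
      ev <- tibble(x = acc$x, y = acc$y, onset_ms = acc$onset,
                   duration_ms = acc$dur)
      ev$x[is.na(ev$x)] <- screen[1] / 2
      ev$y[is.na(ev$y)] <- screen[2] / 2
      stream <- scripted_stream(ev, sampling_hz = model$sampling_hz,
                                screen = screen)
      n <- nrow(stream)
      if (n > 0L) {
        if (model$jitter_px > 0) {
          stream$x_px <- stream$x_px + rnorm(n, 0, model$jitter_px)
          stream$y_px <- stream$y_px + rnorm(n, 0, model$jitter_px)
        }
        if (model$dropout_rate > 0) {
          stream$valid <- stream$valid & runif(n) >= model$dropout_rate
        }
      }
    }
    list(truth = bind_rows(truth), transitions = bind_rows(trans),
         fixations = fixations, stream = stream)
  })
}

# simulate one trial: lay down events phase by phase and resolve each
# transition with the engine itself (closed loop)
.sim_trial <- function(trial, model, t0, acc, screen) {
  centers <- roi_centers(trial$rois)
  ph <- trial$phases
  id <- trial$trial_id
  construct_phase <- switch(trial$task, RJA = 3L, IJA_request = 3L,
                            IJA_comment = 2L, training = 4L, NA_integer_)
  p_construct <- switch(trial$task, RJA = model$p_rja,
                        IJA_request = model$p_request,
                        IJA_comment = model$p_comment,
                        training = model$p_request, NA_real_)
  alt_target <- paste0(
    switch(trial$task, IJA_request = "Tablet", IJA_comment = "Object",
           training = "Tablet", "Target"),
    if (trial$direction == "left") "Left" else "Right")

  complied_init <- NA; complied_con <- NA
  lat_init <- NA_real_; lat_con <- NA_real_

  recs <- list()
  cur <- ph$phase[1L]
  onset <- t0
  while (!is.na(cur)) {
    row <- ph[ph$phase == cur, , drop = FALSE]
    trig <- row$trigger[[1L]]
    dur <- row$duration_ms[1L]
    t_end_max <- if (is.na(dur)) Inf else onset + dur

    if (!is.null(trig) && trig$kind == "fixation" &&
        trig$roi == "AttentionGetter") {
      L <- .sim_latency(model, 100, 2000)
      start <- max(onset + L, .sim_end(acc) + 30)
      .sim_wander(acc, id, cur, screen, onset, start - 30)
      .sim_add(acc, id, cur, "AttentionGetter",
               centers$x[centers$id == "AttentionGetter"],
               centers$y[centers$id == "AttentionGetter"], start, 300)
    } else if (!is.null(trig) && trig$kind == "fixation") {
      comply <- runif(1L) < model$p_initiate
      latest <- t_end_max - trig$min_fixation_ms - 100
      start <- max(onset + .sim_latency(model, 100, max(100, dur - 600)),
                   .sim_end(acc) + 30)
      if (comply && start <= latest) {
        .sim_wander(acc, id, cur, screen, onset, start - 30)
        .sim_add(acc, id, cur, "Face", centers$x[centers$id == "Face"],
                 centers$y[centers$id == "Face"], start, 600)
        complied_init <- TRUE
        lat_init <- start + trig$min_fixation_ms - onset
      } else {
        .sim_wander(acc, id, cur, screen, onset, t_end_max)
        complied_init <- FALSE
      }
    } else if (!is.null(trig) && trig$kind == "alternation") {
      comply <- runif(1L) < p_construct
      # the face leg cannot start before gaze frees up, so the earliest
      # feasible alternation end depends on how long the face was watched
      lo <- max(500, .sim_end(acc) - onset + 420)
      if (comply && lo <= dur - 200) {
        # alternation ends (target fixation offset) at onset + L
        L <- .sim_latency(model, lo, dur - 200)
        .sim_dwell(acc, id, cur, "Face", centers, onset + L - 330, from = onset)
        .sim_add(acc, id, cur, alt_target,
                 centers$x[centers$id == alt_target],
                 centers$y[centers$id == alt_target], onset + L - 300, 300)
        complied_con <- TRUE
        lat_con <- L
      } else {
        .sim_wander(acc, id, cur, screen, onset, t_end_max)
        complied_con <- FALSE
      }
    } else if (trial$task == "RJA" && cur == 3L) {
      # cue window: a correct response leaves the face for the cued target
      comply <- runif(1L) < model$p_rja
      if (comply) {
        L <- .sim_latency(model, 150, dur - 500)
        .sim_dwell(acc, id, cur, "Face", centers, onset + L - 30, from = onset)
        tgt <- alt_target
        .sim_add(acc, id, cur, tgt, centers$x[centers$id == tgt],
                 centers$y[centers$id == tgt], onset + L, 400)
        .sim_dwell(acc, id, cur, tgt, centers, t_end_max, from = onset)
        complied_con <- TRUE
        lat_con <- L
      } else {
        .sim_dwell(acc, id, cur, "Face", centers, t_end_max, from = onset)
        complied_con <- FALSE
      }
    } else if (trial$task == "RJA" && cur == 2L) {
      # direct gaze; keep fixating the face across the upcoming cue onset
      .sim_dwell(acc, id, cur, "Face", centers, t_end_max + 60, from = onset)
    } else if (trial$task == "training" && cur == 1L) {
      # demonstration: the partner plays each tablet video in turn
      mid <- onset + dur / 2
      .sim_dwell(acc, id, cur, "TabletLeft", centers, mid - 30, from = onset)
      .sim_dwell(acc, id, cur, "TabletRight", centers, t_end_max, from = onset)
    } else if (trial$task %in% c("IJA_request", "training") &&
               cur == max(ph$phase)) {
      # requested video plays: watch it
      .sim_dwell(acc, id, cur, alt_target, centers, t_end_max, from = onset)
    } else {
      .sim_dwell(acc, id, cur, "Face", centers, t_end_max, from = onset)
    }

    rec <- run_phase(row, .sim_fixations(acc), overrides = NULL,
                     phase_onset = onset, trial_id = id,
                     allow_unbounded = is.na(dur),
                     data_end = .sim_end(acc))
    recs[[length(recs) + 1L]] <- rec
    onset <- rec$t_ms
    cur <- if (rec$cause == "timeout") row$on_timeout[1L] else row$on_trigger[1L]
  }

  transitions <- bind_rows(recs)
  truth <- tibble(trial_id = id, task = trial$task, cue = trial$cue,
                  direction = trial$direction, scored = trial$scored,
                  complied_init = complied_init,
                  complied_construct = complied_con,
                  intended_latency_ms = lat_con,
                  intended_init_latency_ms = lat_init,
                  side = trial$direction)
  list(truth = truth, transitions = transitions,
       t_end = transitions$t_ms[nrow(transitions)])
}

#' Deterministic scripted gaze stream
#'
#' Builds a raw gaze-sample stream from a list of non-overlapping fixation
#' events: samples sit at the event's position for its duration
#' (piecewise-stationary), with a linear saccadic transition of 30 ms
#' before each following event; gap time beyond the saccade window is
#' emitted as invalid samples (track loss). Events may name an ROI (centers
#' resolved against `rois`) or give `x` / `y` directly.
#'
#' @param events Tibble with `onset_ms`, `duration_ms` and either `roi` or
#'   `x`, `y`. Must be time-sorted and non-overlapping.
#' @param rois ROI tibble used to resolve `roi` names to centers.
#' @param sampling_hz Sample rate.
#' @param screen Screen size in px.
#' @return Gaze-sample tibble (`t_ms`, `x_px`, `y_px`, `valid`).
#' @examples
#' ev <- tibble::tibble(x = 960, y = 540, onset_ms = 0, duration_ms = 300)
#' nrow(scripted_stream(ev))
#' @export
scripted_stream <- function(events, rois = NULL, sampling_hz = 300,
                            screen = c(1920, 1080)) {
  events <- as_tibble(events)
  if (nrow(events) == 0L) {
    return(tibble(t_ms = numeric(), x_px = numeric(), y_px = numeric(),
                  valid = logical()))
  }
  if (!all(c("x", "y") %in% names(events))) {
    if (is.null(rois) || !"roi" %in% names(events))
      abort("events need x/y columns, or a roi column plus a rois table")
    cen <- roi_centers(rois)
    idx <- match(events$roi, cen$id)
    if (anyNA(idx)) abort("event roi not found in the ROI table")
    events$x <- cen$x[idx]; events$y <- cen$y[idx]
  }
  o <- order(events$onset_ms)
  events <- events[o, ]
  ends <- events$onset_ms + events$duration_ms
  if (nrow(events) > 1L &&
      any(events$onset_ms[-1L] < ends[-nrow(events)] - .ja_eps))
    abort("scripted events must not overlap in time")

  dt <- 1000 / sampling_hz
  segs <- vector("list", 2L * nrow(events))
  for (i in seq_len(nrow(events))) {
    n <- floor((events$duration_ms[i] - 1e-9) / dt) + 1L
    tt <- events$onset_ms[i] + (seq_len(n) - 1L) * dt
    segs[[2L * i - 1L]] <- tibble(t_ms = tt, x_px = events$x[i],
                                  y_px = events$y[i], valid = TRUE)
    if (i < nrow(events)) {
      gs <- ends[i]; ge <- events$onset_ms[i + 1L]
      if (ge - gs > .ja_eps) {
        m <- floor((ge - gs - 1e-9) / dt)
        if (m >= 1L) {
          gt <- gs + seq_len(m) * dt
          gt <- gt[gt < ge - .ja_eps]
          sac_start <- ge - min(30, ge - gs)
          frac <- pmin(1, pmax(0, (gt - sac_start) / (ge - sac_start)))
          in_sac <- gt >= sac_start - .ja_eps
          segs[[2L * i]] <- tibble(
            t_ms = gt,
            x_px = events$x[i] + frac * (events$x[i + 1L] - events$x[i]),
            y_px = events$y[i] + frac * (events$y[i + 1L] - events$y[i]),
            valid = in_sac
          )
        }
      }
    }
  }
  out <- bind_rows(segs)
  out[order(out$t_ms), ]
}
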