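# Scripted transition logs and fixation tables for one trial make the
# scoring rules testable in isolation from the engine.

rja_trial <- make_trial("RJA", "left", cue = "gaze_shift", stimulus_set = "cups")

rja_transitions <- function(trial, cue_onset = 6000, p3_cause = "timeout") {
  tibble::tibble(
    trial_id = trial$trial_id, phase = 0:3,
    cause = c("gaze_fixation", "gaze_fixation", "timeout", p3_cause),
    t_ms = c(300, 4500, cue_onset, cue_onset + 4000),
    latency_ms = c(300, 4200, 1500, 4000),
    scheduled = c(FALSE, FALSE, TRUE, p3_cause == "timeout")
  )
}

# face fixation spanning cue onset, then one fixation at `leave` ms later
rja_fixations <- function(cue_onset = 6000, leave = 800, to = "TargetLeft") {
  tibble::tibble(
    onset_ms = c(cue_onset - 1000, cue_onset + leave),
    offset_ms = c(cue_onset + leave - 30, cue_onset + leave + 400),
    cx_px = 0, cy_px = 0,
    duration_ms = c(1000 + leave - 30, 400),
    roi = c("Face", to)
  )
}

test_that("RJA scores a first fixation from face to the cued target as correct", {
  res <- score_rja(rja_trial, rja_transitions(rja_trial),
                   rja_fixations(to = "TargetLeft"))
  expect_equal(res$rja_outcome, "correct")
  expect_equal(res$latency_ms, 800)
  expect_true(res$valid_for_analysis)
})

test_that("RJA outcome covers distractor, no-leave, and off-target cases", {
  # opposite target: incorrect
  res <- score_rja(rja_trial, rja_transitions(rja_trial),
                   rja_fixations(to = "TargetRight"))
  expect_equal(res$rja_outcome, "incorrect")
  # gaze never leaves the face
  fx <- tibble::tibble(onset_ms = 5000, offset_ms = 10000, cx_px = 0, cy_px = 0,
                       duration_ms = 5000, roi = "Face")
  res2 <- score_rja(rja_trial, rja_transitions(rja_trial), fx)
  expect_equal(res2$rja_outcome, "none")
  expect_true(is.na(res2$latency_ms))
  # first leaving fixation lands on neither target
  res3 <- score_rja(rja_trial, rja_transitions(rja_trial),
                    rja_fixations(to = "none") |>
                      dplyr::mutate(roi = dplyr::na_if(roi, "none")))
  expect_equal(res3$rja_outcome, "none")
  # not on the face at cue onset: none, even if a target is fixated later
  fx4 <- tibble::tibble(onset_ms = c(4800, 6800), offset_ms = c(5800, 7200),
                        cx_px = 0, cy_px = 0, duration_ms = c(1000, 400),
                        roi = c("Face", "TargetLeft"))  # face ends before cue
  res4 <- score_rja(rja_trial, rja_transitions(rja_trial), fx4)
  expect_equal(res4$rja_outcome, "none")
})

test_that("RJA scoring agrees with exhaustive label-sequence enumeration", {
  cue <- 6000
  outcomes <- c(TargetLeft = "correct", TargetRight = "incorrect",
                Hand = "none", none = "none")
  for (first in names(outcomes)) {
    for (second in names(outcomes)) {
      fx <- tibble::tibble(
        onset_ms = c(cue - 1000, cue + 500, cue + 1000),
        offset_ms = c(cue + 470, cue + 970, cue + 1400),
        cx_px = 0, cy_px = 0,
        duration_ms = c(1470, 470, 400),
        roi = c("Face",
                ifelse(first == "none", NA_character_, first),
                ifelse(second == "none", NA_character_, second))
      )
      res <- score_rja(rja_trial, rja_transitions(rja_trial), fx)
      # the first non-face fixation decides
      expect_equal(res$rja_outcome, unname(outcomes[first]))
    }
  }
})

test_that("an overridden cue phase invalidates the RJA trial", {
  res <- score_rja(rja_trial, rja_transitions(rja_trial, p3_cause = "override"),
                   rja_fixations())
  expect_false(res$valid_for_analysis)
})

ija_transitions <- function(trial, construct, cause, latency = 2340) {
  ph <- trial$phases$phase
  n <- length(ph)
  ends <- cumsum(c(300, ifelse(is.na(trial$phases$duration_ms[-1]), 0,
                               trial$phases$duration_ms[-1])))
  tb <- tibble::tibble(trial_id = trial$trial_id, phase = ph,
                       cause = "timeout", t_ms = ends,
                       latency_ms = c(300, diff(ends)), scheduled = TRUE)
  i <- which(ph == construct)
  tb$cause[i] <- cause
  tb$scheduled[i] <- FALSE
  if (cause != "timeout") tb$latency_ms[i] <- latency
  tb
}

test_that("IJA success requires a gaze-alternation cause on the construct phase", {
  req <- make_trial("IJA_request", "left", stimulus_set = "video_pair_1")
  res <- score_ija(req, ija_transitions(req, 3L, "gaze_alternation", 2340))
  expect_true(res$ija_success)
  expect_equal(res$latency_ms, 2340)
  expect_true(res$valid_for_analysis)

  res2 <- score_ija(req, ija_transitions(req, 3L, "timeout"))
  expect_false(res2$ija_success)
  expect_true(is.na(res2$latency_ms))
  expect_true(res2$valid_for_analysis)

  res3 <- score_ija(req, ija_transitions(req, 3L, "override"))
  expect_false(res3$valid_for_analysis)
  expect_true(is.na(res3$ija_success))

  com <- make_trial("IJA_comment", "right", stimulus_set = "spider")
  res4 <- score_ija(com, ija_transitions(com, 2L, "gaze_alternation", 1800))
  expect_true(res4$ija_success)
  expect_equal(res4$latency_ms, 1800)
})

test_that("engine-run IJA latency equals the alternation pair's terminal offset", {
  req <- make_trial("IJA_request", "left", stimulus_set = "video_pair_1")
  cen <- roi_centers(req$rois)
  # comply with every trigger by script: attention-getter, face, then
  # face -> tablet alternation inside phase 3
  ev <- tibble::tibble(
    roi = c("AttentionGetter", "Face", "TabletLeft"),
    onset_ms = c(200, 700, 7500),
    duration_ms = c(300, 6500, 400)
  )
  s <- scripted_stream(ev, rois = req$rois)
  tr <- run_trial(req, samples = s)
  p3 <- tr[tr$phase == 3L, ]
  expect_equal(p3$cause, "gaze_alternation")
  res <- score_ija(req, tr)
  expect_true(res$ija_success)
  # phase 3 onset is the phase-2 transition; alternation ends at the tablet
  # fixation's offset (7900 ms)
  p2 <- tr[tr$phase == 2L, ]
  expect_equal(res$latency_ms, 7900 - p2$t_ms, tolerance = 5)
})

test_that("session summaries aggregate over valid trials only", {
  b <- build_battery(1)
  m <- participant_model()
  sim <- simulate_session(b, m, seed = 4, return_stream = FALSE)
  res <- score_session(b, sim$transitions, sim$fixations)
  expect_equal(nrow(res), 32L)
  s <- summarize_session(res, sim$transitions)
  expect_equal(s$by_construct$success_rate, c(1, 1, 1))
  expect_true(all(s$by_construct$n_valid == c(16, 8, 8)))
  # cause histogram conserves the number of executed phases
  expect_equal(sum(s$cause_histogram$n_transitions), nrow(sim$transitions))
  # tidy/glance accessors
  expect_equal(nrow(generics::tidy(s)), 3L)
  g <- generics::glance(s)
  expect_equal(g$rja_rate, 1)

  # arithmetic: 12 of 16 correct -> 0.75
  res2 <- res
  flip <- which(res2$task == "RJA")[1:4]
  res2$rja_outcome[flip] <- "none"
  expect_equal(summarize_session(res2)$by_construct$success_rate[1], 0.75)

  # all overridden -> undefined proportions, not zero
  res3 <- res
  res3$valid_for_analysis <- FALSE
  s3 <- summarize_session(res3)
  expect_true(all(is.na(s3$by_construct$success_rate)))
  expect_true(all(s3$by_construct$n_valid == 0))
})

test_that("timeouts and overrides never contribute to success counts", {
  b <- build_battery(2)
  withr::with_seed(31, {
    m <- participant_model(p_initiate = 0.6, p_rja = 0.5, p_request = 0.5,
                           p_comment = 0.5)
    sim <- simulate_session(b, m, seed = 17, return_stream = FALSE)
    res <- score_session(b, sim$transitions, sim$fixations)
    tr <- sim$transitions
    for (i in which(res$task != "RJA")) {
      construct <- if (res$task[i] == "IJA_request") 3L else 2L
      cause <- tr$cause[tr$trial_id == res$trial_id[i] & tr$phase == construct]
      if (cause == "timeout") expect_false(res$ija_success[i])
      if (cause == "gaze_alternation") expect_true(res$ija_success[i])
    }
    # latency bounds: IJA latencies within the 7 s timeframe, RJA within 4 s
    expect_true(all(res$latency_ms[res$task != "RJA"] <= 7000, na.rm = TRUE))
    expect_true(all(res$latency_ms[res$task == "RJA"] <= 4000, na.rm = TRUE))
    expect_true(all(res$latency_ms >= 0, na.rm = TRUE))
  })
})
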