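face_trig <- trigger_fixation("Face", 200)

test_that("fixation trigger fires when threshold dwell accumulates in-phase", {
  # 250 ms face fixation entering the phase: fires 200 ms after entry
  fx <- tibble::tibble(onset_ms = 1000, offset_ms = 1250, cx_px = 0, cy_px = 0,
                       duration_ms = 250, roi = "Face")
  hit <- eval_fixation_trigger(fx, face_trig, phase_onset = 0, phase_end = 4000)
  expect_true(hit$fired)
  expect_equal(hit$fire_time, 1200)
  # sub-threshold fixation never fires
  fx$offset_ms <- 1150; fx$duration_ms <- 150
  expect_false(eval_fixation_trigger(fx, face_trig, 0, 4000)$fired)
  # long fixation outside the ROI never fires
  fx2 <- tibble::tibble(onset_ms = 1000, offset_ms = 1400, cx_px = 0, cy_px = 0,
                        duration_ms = 400, roi = "TargetLeft")
  expect_false(eval_fixation_trigger(fx2, face_trig, 0, 4000)$fired)
})

test_that("a fixation straddling phase onset only counts its within-phase part", {
  # fixation [ -500, 300 ] relative to onset 1000: within-phase dwell 300 ms
  fx <- tibble::tibble(onset_ms = 500, offset_ms = 1300, cx_px = 0, cy_px = 0,
                       duration_ms = 800, roi = "Face")
  hit <- eval_fixation_trigger(fx, face_trig, phase_onset = 1000, phase_end = 5000)
  expect_true(hit$fired)
  expect_equal(hit$fire_time, 1200)  # onset + 200, not instantaneous
  # only 100 ms falls inside the phase: no fire
  fx$offset_ms <- 1100
  expect_false(eval_fixation_trigger(fx, face_trig, 1000, 5000)$fired)
})

alt_trig <- trigger_alternation("Face", "Target")

test_that("alternation fires at the target fixation's offset after a face fixation", {
  fx <- fixations_from_labels(c("Face", "Target"))
  hit <- eval_alternation_trigger(fx, alt_trig, 0, 7000)
  expect_true(hit$fired)
  expect_equal(hit$fire_time, fx$offset_ms[2])
})

test_that("an intervening fixation resets the sequence without ending the phase", {
  fx <- fixations_from_labels(c("Face", "Hand", "Target", "Face", "Target"))
  hit <- eval_alternation_trigger(fx, alt_trig, 0, 7000)
  expect_true(hit$fired)
  expect_equal(hit$fire_time, fx$offset_ms[5])  # the later clean pair
  # same-ROI re-fixation is not a deviation
  fx2 <- fixations_from_labels(c("Face", "Face", "Target"))
  hit2 <- eval_alternation_trigger(fx2, alt_trig, 0, 7000)
  expect_true(hit2$fired)
  expect_equal(hit2$fire_time, fx2$offset_ms[3])
})

test_that("alternation agrees with the automaton oracle on all short label sequences", {
  alphabet <- c("Face", "Target", "Hand", "none")
  for (len in 1:4) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), len), stringsAsFactors = FALSE))
    for (r in seq_len(nrow(grid))) {
      labels <- as.character(grid[r, ])
      fx <- fixations_from_labels(labels)
      hit <- eval_alternation_trigger(fx, alt_trig, 0, Inf)
      k <- oracle_alternation_index(labels)
      expect_equal(hit$fired, k > 0L)
      if (k > 0L) expect_equal(hit$fire_time, fx$offset_ms[k])
    }
  }
})

test_that("either-order alternation accepts target-then-face pairs", {
  both <- trigger_alternation("Face", "Target", either_order = TRUE)
  fx <- fixations_from_labels(c("Target", "Face"))
  expect_false(eval_alternation_trigger(fx, alt_trig, 0, Inf)$fired)
  expect_true(eval_alternation_trigger(fx, both, 0, Inf)$fired)
})

test_that("run_phase resolves cause precedence and timeouts", {
  phase <- phase_spec(1L, 4000, face_trig, on_trigger = 2L, on_timeout = 2L)
  # no face fixation: timeout at the timeframe
  rec <- run_phase(phase, empty_fixations() |> dplyr::mutate(roi = character(0)),
                   phase_onset = 0)
  expect_equal(rec$cause, "timeout")
  expect_equal(rec$latency_ms, 4000)
  expect_false(rec$scheduled)
  # override before any trigger wins
  fx <- tibble::tibble(onset_ms = 2000, offset_ms = 2500, cx_px = 0, cy_px = 0,
                       duration_ms = 500, roi = "Face")
  rec2 <- run_phase(phase, fx, overrides = tibble::tibble(t_ms = 1200),
                    phase_onset = 0)
  expect_equal(rec2$cause, "override")
  expect_equal(rec2$latency_ms, 1200)
  # gaze trigger at the timeframe boundary beats the timeout
  fx3 <- tibble::tibble(onset_ms = 3799, offset_ms = 4300, cx_px = 0, cy_px = 0,
                        duration_ms = 501, roi = "Face")
  rec3 <- run_phase(phase, fx3, phase_onset = 0)
  expect_equal(rec3$cause, "gaze_fixation")
  expect_equal(rec3$t_ms, 3999)
  fx4 <- tibble::tibble(onset_ms = 3800, offset_ms = 4300, cx_px = 0, cy_px = 0,
                        duration_ms = 500, roi = "Face")
  rec4 <- run_phase(phase, fx4, phase_onset = 0)
  expect_equal(rec4$cause, "gaze_fixation")
  expect_equal(rec4$t_ms, 4000)
  # one ms past the timeframe: timeout
  fx5 <- tibble::tibble(onset_ms = 3801, offset_ms = 4300, cx_px = 0, cy_px = 0,
                        duration_ms = 499, roi = "Face")
  rec5 <- run_phase(phase, fx5, phase_onset = 0)
  expect_equal(rec5$cause, "timeout")
})

test_that("non-contingent phases end by scheduled timeout", {
  phase <- phase_spec(2L, 1500, NULL, on_trigger = 3L, on_timeout = 3L)
  rec <- run_phase(phase, empty_fixations(), phase_onset = 100)
  expect_equal(rec$cause, "timeout")
  expect_true(rec$scheduled)
  expect_equal(rec$t_ms, 1600)
})

test_that("a phase that could wait forever is an error unless explicitly allowed", {
  endless <- phase_spec(9L, NA_real_, NULL)
  expect_error(run_phase(endless, empty_fixations(), phase_onset = 0),
               "wait forever")
  ag <- phase_spec(0L, NA_real_, trigger_fixation("AttentionGetter", 100))
  fx <- empty_fixations() |> dplyr::mutate(roi = character(0))
  rec <- run_phase(ag, fx, phase_onset = 0, allow_unbounded = TRUE,
                   data_end = 2500)
  expect_equal(rec$cause, "timeout")
  expect_true(rec$scheduled)
  expect_equal(rec$t_ms, 2500)
})

test_that("unresponsive streams reproduce the per-task maximum durations", {
  b <- build_battery(1)
  expected <- c(RJA = 9500, IJA_request = 26000, IJA_comment = 14000,
                training = 52000)
  for (tk in names(expected)) {
    trial <- b$spec[[which(b$task == tk)[1]]]
    tr <- run_trial(trial)
    expect_equal(elapsed_after_ag(tr), unname(expected[tk]))
    expect_true(all(tr$cause == "timeout"))
  }
})

test_that("every executed phase yields exactly one record with one cause", {
  b <- build_battery(3)
  withr::with_seed(99, {
    for (rep in 1:5) {
      m <- participant_model(p_initiate = runif(1), p_rja = runif(1),
                             p_request = runif(1), p_comment = runif(1))
      sim <- simulate_session(b, m, seed = rep, return_stream = FALSE)
      tr <- sim$transitions
      expect_false(any(duplicated(tr[c("trial_id", "phase")])))
      expect_true(all(tr$cause %in%
                        c("gaze_fixation", "gaze_alternation", "timeout", "override")))
      # timeframe ceiling: gaze latencies never exceed the phase duration
      for (i in seq_len(nrow(b))) {
        ph <- b$spec[[i]]$phases
        ti <- dplyr::left_join(tr[tr$trial_id == b$trial_id[i], ],
                               ph[c("phase", "duration_ms")], by = "phase")
        fin <- !is.na(ti$duration_ms)
        expect_true(all(ti$latency_ms[fin] <= ti$duration_ms[fin] + 1e-6))
        expect_true(all(ti$latency_ms >= 0))
      }
    }
  })
})

test_that("one override command advances exactly one phase", {
  b <- build_battery(1)
  trial <- b$spec[[which(b$task == "IJA_request")[1]]]
  ov <- tibble::tibble(t_ms = 500, note = "drift")
  tr <- run_trial(trial, overrides = ov)
  expect_equal(sum(tr$cause == "override"), 1L)
  expect_equal(tr$cause[1], "override")
  expect_equal(tr$cause[2], "timeout")  # next phase runs its own course
})

test_that("identical inputs produce identical transition sequences", {
  b <- build_battery(2)
  m <- participant_model(p_initiate = 0.7, p_rja = 0.5, p_request = 0.5,
                         p_comment = 0.5, jitter_px = 3, dropout_rate = 0.02)
  sim <- simulate_session(b, m, seed = 5)
  t1 <- run_session(b, samples = sim$stream)
  t2 <- run_session(b, samples = sim$stream)
  expect_identical(t1, t2)
})
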