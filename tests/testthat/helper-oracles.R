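# Independent oracles and fixture builders used across the suite.

# Brute-force maximal-window fixation oracle: for each start sample, the
# maximal end is found by testing every window against the dispersion and
# gap predicates with full recomputation; a window is kept iff its duration
# (last sample + one sampling interval - first sample) reaches the minimum.
oracle_fixations <- function(samples, max_dispersion_px = 60,
                             min_duration_ms = 60, max_gap_ms = 75) {
  dt <- stats::median(diff(samples$t_ms))
  keep <- samples$valid & is.finite(samples$x_px) & is.finite(samples$y_px)
  t <- samples$t_ms[keep]; x <- samples$x_px[keep]; y <- samples$y_px[keep]
  n <- length(t)
  ok_window <- function(i, j) {
    if (j > i && any(diff(t[i:j]) > max_gap_ms + 1e-6)) return(FALSE)
    (max(x[i:j]) - min(x[i:j])) + (max(y[i:j]) - min(y[i:j])) <=
      max_dispersion_px + 1e-6
  }
  out <- list(); i <- 1L
  while (i <= n) {
    j <- i
    for (jj in i:n) {
      if (ok_window(i, jj)) j <- jj else break
    }
    if (t[j] + dt - t[i] >= min_duration_ms - 1e-6) {
      out[[length(out) + 1L]] <- c(t[i], t[j] + dt, mean(x[i:j]), mean(y[i:j]))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) {
    return(tibble::tibble(onset_ms = numeric(), offset_ms = numeric(),
                          cx_px = numeric(), cy_px = numeric()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(onset_ms = m[, 1], offset_ms = m[, 2],
                 cx_px = m[, 3], cy_px = m[, 4])
}

# Two-state automaton oracle for the gaze-alternation trigger: returns the
# 1-based index of the fixation completing the first uninterrupted
# Face -> Target pair, or 0; the armed state resets on any label outside
# the pair.
oracle_alternation_index <- function(labels, face = "Face", target = "Target") {
  armed <- FALSE
  for (k in seq_along(labels)) {
    if (armed && identical(labels[k], target)) return(k)
    armed <- identical(labels[k], face)
  }
  0L
}

# Turn a label sequence into back-to-back fixations (300 ms each, 30 ms
# saccade gaps) with the labels attached directly.
fixations_from_labels <- function(labels, start = 0, dur = 300, gap = 30) {
  n <- length(labels)
  onset <- start + (seq_len(n) - 1L) * (dur + gap)
  tibble::tibble(onset_ms = onset, offset_ms = onset + dur,
                 cx_px = 0, cy_px = 0, duration_ms = dur,
                 roi = ifelse(labels == "none", NA_character_, labels))
}

# Regular zero-noise sample stream at one position.
stationary_stream <- function(x, y, onset, duration, hz = 300, valid = TRUE) {
  dt <- 1000 / hz
  n <- floor((duration - 1e-9) / dt) + 1L
  tibble::tibble(t_ms = onset + (seq_len(n) - 1L) * dt,
                 x_px = x, y_px = y, valid = valid)
}

# Random piecewise-stationary stream with known generating segments.
random_gaze_stream <- function(n_segments = 6, hz = 300, jitter = 3,
                               dropout = 0.05) {
  t <- 0
  pieces <- list()
  for (k in seq_len(n_segments)) {
    dur <- runif(1, 80, 600)
    s <- stationary_stream(runif(1, 100, 1800), runif(1, 100, 1000), t, dur,
                           hz = hz)
    s$x_px <- s$x_px + rnorm(nrow(s), 0, jitter)
    s$y_px <- s$y_px + rnorm(nrow(s), 0, jitter)
    pieces[[k]] <- s
    t <- t + dur + runif(1, 20, 200)
  }
  out <- dplyr::bind_rows(pieces)
  out$valid <- runif(nrow(out)) >= dropout
  out[seq_len(min(nrow(out), 1000L)), ]
}

empty_fixations <- function() {
  tibble::tibble(onset_ms = numeric(), offset_ms = numeric(),
                 cx_px = numeric(), cy_px = numeric(), duration_ms = numeric())
}

# Elapsed trial time excluding the untimed attention-getter: from the end of
# phase 0 to the terminal transition.
elapsed_after_ag <- function(transitions) {
  transitions$t_ms[nrow(transitions)] - transitions$t_ms[1L]
}
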