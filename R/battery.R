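#' Default ROI layout for a trial
#'
#' The engine ships a configurable ROI template expressed as fractions of a
#' 1920x1080 reference screen: the partner's face in the upper center, the
#' two object/tablet targets on the table at left and right, suddenly
#' appearing objects in the top corners (comment/reference trials), and a
#' 200x200 px attention-getter centered 15% of the screen size in from the
#' bottom corner on the trial's counterbalanced side -- inset because gaze
#' estimation degrades near the screen edges. No two ROIs of a trial
#' overlap.
#'
#' @param task Task name, one of `"greeting"`, `"training"`, `"RJA"`,
#'   `"IJA_request"`, `"IJA_comment"`.
#' @param direction `"left"` or `"right"` (counterbalanced side).
#' @param screen Screen size in px, `c(width, height)`.
#' @return ROI tibble (see [roi_table()]).
#' @export
default_rois <- function(task, direction = "left", screen = c(1920, 1080)) {
  sx <- screen[1] / 1920; sy <- screen[2] / 1080
  rect <- function(x0, y0, x1, y1) c(x0 * sx, y0 * sy, x1 * sx, y1 * sy)

  face <- rect(810, 120, 1110, 420)
  tgt_l <- rect(400, 640, 700, 940)
  tgt_r <- rect(1220, 640, 1520, 940)
  obj_l <- rect(0, 0, 300, 300)
  obj_r <- rect(1620, 0, 1920, 300)
  ag_c <- if (direction == "left") {
    c(0.15 * screen[1], screen[2] - 0.15 * screen[2])
  } else {
    c(screen[1] - 0.15 * screen[1], screen[2] - 0.15 * screen[2])
  }
  ag <- c(ag_c[1] - 100 * sx, ag_c[2] - 100 * sy,
          ag_c[1] + 100 * sx, ag_c[2] + 100 * sy)

  rows <- list(c(id = "Face", role = "Face"))
  rects <- list(face)
  if (task %in% c("RJA")) {
    rows <- c(rows, list(c("TargetLeft", "TargetLeft"),
                         c("TargetRight", "TargetRight")))
    rects <- c(rects, list(tgt_l, tgt_r))
  }
  if (task %in% c("IJA_request", "training", "greeting")) {
    rows <- c(rows, list(c("TabletLeft", "TabletLeft"),
                         c("TabletRight", "TabletRight")))
    rects <- c(rects, list(tgt_l, tgt_r))
  }
  if (task == "IJA_comment") {
    if (direction == "left") {
      rows <- c(rows, list(c("ObjectLeft", "ObjectLeft")))
      rects <- c(rects, list(obj_l))
    } else {
      rows <- c(rows, list(c("ObjectRight", "ObjectRight")))
      rects <- c(rects, list(obj_r))
    }
  }
  if (task != "greeting") {
    rows <- c(rows, list(c("AttentionGetter", "AttentionGetter")))
    rects <- c(rects, list(ag))
  }
  m <- do.call(rbind, rects)
  roi_table(id = vapply(rows, `[`, "", 1L), role = vapply(rows, `[`, "", 2L),
            x0 = m[, 1], y0 = m[, 2], x1 = m[, 3], y1 = m[, 4],
            screen = screen)
}

# phase-chain templates; durations in ms are the battery's scripted timing:
# initial looking-down phase 4 s (200 ms Face fixation), direct-gaze response
# 1.5 s, RJA cue window 4 s, IJA alternation timeframe 7 s, request response
# 3.5 s + 10 s video, comment response 3 s, greeting 10 s, training demo 26 s
# so the training cap is 52 s.
.ja_phase_chain <- function(task, direction) {
  ag <- function(i, nxt) {
    phase_spec(i, NA_real_, trigger_fixation("AttentionGetter", 100),
               on_trigger = nxt, on_timeout = nxt)
  }
  face <- function(i, nxt) {
    phase_spec(i, 4000, trigger_fixation("Face", 200),
               on_trigger = nxt, on_timeout = nxt)
  }
  fixed <- function(i, dur, nxt = NA_integer_) {
    phase_spec(i, dur, NULL, on_trigger = nxt, on_timeout = nxt)
  }
  alt <- function(i, dur, target, nxt) {
    phase_spec(i, dur, trigger_alternation("Face", target),
               on_trigger = nxt, on_timeout = nxt)
  }
  side <- function(stub) paste0(stub, if (direction == "left") "Left" else "Right")
  switch(task,
    RJA = bind_rows(ag(0L, 1L), face(1L, 2L), fixed(2L, 1500, 3L),
                    fixed(3L, 4000)),
    IJA_request = bind_rows(ag(0L, 1L), face(1L, 2L), fixed(2L, 1500, 3L),
                            alt(3L, 7000, side("Tablet"), 4L),
                            fixed(4L, 3500, 5L), fixed(5L, 10000)),
    IJA_comment = bind_rows(ag(0L, 1L), face(1L, 2L),
                            alt(2L, 7000, side("Object"), 3L),
                            fixed(3L, 3000)),
    greeting = fixed(1L, 10000),
    training = bind_rows(ag(0L, 1L), fixed(1L, 26000, 2L), face(2L, 3L),
                         fixed(3L, 1500, 4L),
                         alt(4L, 7000, side("Tablet"), 5L),
                         fixed(5L, 3500, 6L), fixed(6L, 10000)),
    abort(paste0("unknown task: ", task))
  )
}

#' Build one trial specification
#'
#' Assembles the declarative description of a single stimulus: its phase
#' chain with trigger specs and scripted durations, its ROI set, and its
#' counterbalancing attributes. Per-task timing (excluding the untimed
#' attention-getter): RJA 4 + 1.5 + 4 s (max 9.5 s); IJA-Request
#' 4 + 1.5 + 7 + 3.5 + 10 s (max 26 s); IJA-Comment/Reference 4 + 7 + 3 s
#' (max 14 s); greeting 10 s; training capped at 52 s.
#'
#' @param task Task name (see [default_rois()]).
#' @param direction Counterbalanced side, `"left"` or `"right"`.
#' @param cue RJA referential cue, `"gaze_shift"` or `"head_turn"` (RJA
#'   only).
#' @param stimulus_set Object-pair / video-pair / moving-object identifier.
#' @param screen Screen size in px.
#' @param trial_id Identifier; derived from the attributes when `NULL`.
#' @return A `ja_trial` object: a list with fields `trial_id`, `task`,
#'   `cue`, `direction`, `stimulus_set`, `phases`, `rois`, `scored`,
#'   `max_duration_ms` (sum of finite phase durations, attention-getter
#'   excluded).
#' @examples
#' tr <- make_trial("RJA", "left", cue = "head_turn", stimulus_set = "cups")
#' tr$phases
#' @export
make_trial <- function(task, direction = "left", cue = NULL,
                       stimulus_set = NULL, screen = c(1920, 1080),
                       trial_id = NULL) {
  task <- match.arg(task, .ja_tasks)
  direction <- match.arg(direction, .ja_directions)
  if (task == "RJA") {
    if (is.null(cue)) abort("RJA trials require a cue (gaze_shift or head_turn)")
    cue <- match.arg(cue, .ja_cues)
  } else if (!is.null(cue)) {
    abort(paste0("cue is only meaningful for RJA trials, not ", task))
  }
  phases <- .ja_phase_chain(task, direction)
  rois <- default_rois(task, direction, screen)
  trial_id <- trial_id %||%
    paste(c(task, cue, direction, stimulus_set), collapse = "_")
  structure(list(
    trial_id = trial_id, task = task, cue = cue %||% NA_character_,
    direction = direction, stimulus_set = stimulus_set %||% NA_character_,
    phases = phases, rois = rois, scored = task %in% .ja_scored_tasks,
    max_duration_ms = sum(phases$duration_ms, na.rm = TRUE)
  ), class = "ja_trial")
}

#' @export
print.ja_trial <- function(x, ...) {
  cat("<ja_trial> ", x$trial_id, "\n", sep = "")
  cat("  task: ", x$task,
      if (!is.na(x$cue)) paste0(" (", x$cue, ")"),
      ", direction: ", x$direction,
      ", max ", x$max_duration_ms / 1000, " s (excl. attention-getter)\n",
      sep = "")
  invisible(x)
}

# the fixed trial multiset: identical for every seed, only order varies
.ja_trial_roster <- function() {
  rja <- tidyr::expand_grid(
    task = "RJA",
    cue = .ja_cues, direction = .ja_directions,
    stimulus_set = c("cups", "sunglasses", "hats", "balls")
  )
  req <- tidyr::expand_grid(
    task = "IJA_request", cue = NA_character_, direction = .ja_directions,
    stimulus_set = paste0("video_pair_", 1:4)
  )
  com <- tidyr::expand_grid(
    task = "IJA_comment", cue = NA_character_, direction = .ja_directions,
    stimulus_set = c("spider", "parrot", "swinging_ball", "snake")
  )
  bind_rows(rja, req, com)
}

# seeded within-block order forbidding runs of 3+ same-task trials
.ja_interleave <- function(block_rows) {
  repeat {
    ord <- sample.int(nrow(block_rows))
    tk <- block_rows$task[ord]
    runs <- rle(tk)$lengths
    if (max(runs) < 3L) return(block_rows[ord, , drop = FALSE])
  }
}

#' Build the full counterbalanced battery
#'
#' Constructs the 32-stimulus battery: 16 RJA (8 gaze-shift, 8 head-turn; 4
#' trials per cue-by-direction cell; four object pairs each appearing in 4
#' trials), 8 IJA-Request (four video pairs, each in 2 trials) and 8
#' IJA-Comment/Reference (four moving objects, each in 2 trials), organised
#' into 4 blocks of 8 stimuli (4 RJA + 2 IJA-Request + 2 IJA-Comment) with
#' directions balanced left/right overall, per task, and per block. A
#' greeting (10 s) and an IJA-Request training trial (max 52 s) are
#' prepended before block 1 and excluded from scoring.
#'
#' The seed only permutes presentation order within the counterbalancing
#' constraints: trials are dealt into blocks with directions balanced, then
#' interleaved within each block under a constrained shuffle that forbids
#' three consecutive same-task stimuli. The trial multiset is identical for
#' every seed.
#'
#' @param seed Integer seed for the order randomization.
#' @param screen Screen size in px.
#' @param include_intro Prepend the greeting and training trials.
#' @return A `ja_battery`: a tibble with one row per presented trial
#'   (`position`, `block`, `trial_id`, `task`, `cue`, `direction`,
#'   `stimulus_set`, `scored`, and the full `ja_trial` in list-column
#'   `spec`), with the seed and screen stored as attributes.
#' @examples
#' b <- build_battery(seed = 1)
#' dplyr::count(b, task)
#' @export
build_battery <- function(seed = 1L, screen = c(1920, 1080),
                          include_intro = TRUE) {
  roster <- .ja_trial_roster()
  blocks <- withr::with_seed(as.integer(seed), {
    assign_blocks <- function(rows, per_block_per_dir) {
      out <- rows[0, ]
      for (dir in .ja_directions) {
        d <- rows[rows$direction == dir, , drop = FALSE]
        d <- d[sample.int(nrow(d)), , drop = FALSE]
        d$block <- rep(1:4, each = per_block_per_dir)
        out <- bind_rows(out, d)
      }
      out
    }
    dealt <- bind_rows(
      assign_blocks(roster[roster$task == "RJA", ], 2L),
      assign_blocks(roster[roster$task == "IJA_request", ], 1L),
      assign_blocks(roster[roster$task == "IJA_comment", ], 1L)
    )
    bind_rows(lapply(1:4, function(b) {
      .ja_interleave(dealt[dealt$block == b, , drop = FALSE])
    }))
  })

  intro <- tibble(task = c("greeting", "training"), cue = NA_character_,
                  direction = c("left", "left"),
                  stimulus_set = NA_character_, block = 0L)
  tab <- if (include_intro) bind_rows(intro, blocks) else blocks
  tab$position <- seq_len(nrow(tab))
  tab$spec <- purrr::pmap(
    list(tab$task, tab$direction, tab$cue, tab$stimulus_set),
    function(task, direction, cue, set) {
      make_trial(task, direction,
                 cue = if (is.na(cue)) NULL else cue,
                 stimulus_set = if (is.na(set)) NULL else set,
                 screen = screen)
    }
  )
  tab$trial_id <- purrr::map_chr(tab$spec, "trial_id")
  tab$scored <- purrr::map_lgl(tab$spec, "scored")
  tab <- tab[, c("position", "block", "trial_id", "task", "cue", "direction",
                 "stimulus_set", "scored", "spec")]
  structure(tab, class = c("ja_battery", class(tab)),
            seed = as.integer(seed), screen = screen)
}

#' Battery composition table
#'
#' Counts trials by block, task and direction -- the quantities the
#' counterbalancing constraints fix.
#'
#' @param battery A `ja_battery`.
#' @return Tibble of counts.
#' @export
battery_composition <- function(battery) {
  battery |>
    as_tibble() |>
    filter(.data$scored) |>
    count(.data$block, .data$task, .data$direction, name = "n_trials")
}

#' Validate battery counterbalancing invariants
#'
#' Checks every structural constraint of the battery design and aborts with
#' a named violation on the first failure: 32 scored stimuli (16 RJA, 8
#' IJA-Request, 8 IJA-Comment/Reference); 4 blocks of 8 with task histogram
#' 4/2/2; directions balanced 16/16 overall and equally within each task;
#' RJA cues balanced 8/8 with 4 trials per cue-by-direction cell; each RJA
#' object pair in 4 trials, each IJA-Request video pair and each
#' IJA-Comment object in 2; per-task phase-duration sums of 9.5 / 26 / 14 s.
#'
#' @param battery A `ja_battery`.
#' @return The battery, invisibly, if valid.
#' @export
validate_battery <- function(battery) {
  fail <- function(what) abort(paste0("battery invariant violated: ", what))
  b <- as_tibble(battery)
  s <- b[b$scored, ]
  if (nrow(s) != 32L) fail("32 scored stimuli required")
  comp <- table(s$task)
  if (!identical(as.integer(comp[c("RJA", "IJA_request", "IJA_comment")]),
                 c(16L, 8L, 8L)))
    fail("task composition must be 16 RJA / 8 IJA-Request / 8 IJA-Comment")
  for (blk in 1:4) {
    tb <- table(factor(s$task[s$block == blk], levels = .ja_scored_tasks))
    if (!identical(as.integer(tb), c(4L, 2L, 2L)))
      fail(paste0("block ", blk, " must contain 4 RJA + 2 IJA-Request + 2 IJA-Comment"))
    db <- table(factor(s$direction[s$block == blk], levels = .ja_directions))
    if (!identical(as.integer(db), c(4L, 4L)))
      fail(paste0("block ", blk, " directions must be balanced 4 left / 4 right"))
  }
  for (tk in .ja_scored_tasks) {
    d <- table(factor(s$direction[s$task == tk], levels = .ja_directions))
    if (d["left"] != d["right"]) fail(paste0(tk, " directions must be balanced"))
  }
  rja <- s[s$task == "RJA", ]
  cue_cells <- table(rja$cue, rja$direction)
  if (!all(cue_cells == 4L))
    fail("RJA must have 4 trials per cue x direction cell")
  if (!all(table(rja$stimulus_set) == 4L))
    fail("each RJA object pair must appear in 4 trials")
  if (!all(table(s$stimulus_set[s$task == "IJA_request"]) == 2L))
    fail("each IJA-Request video pair must appear in 2 trials")
  if (!all(table(s$stimulus_set[s$task == "IJA_comment"]) == 2L))
    fail("each IJA-Comment object must appear in 2 trials")
  expected_max <- c(RJA = 9500, IJA_request = 26000, IJA_comment = 14000)
  got <- vapply(battery$spec[battery$scored], `[[`, 0, "max_duration_ms")
  if (!all(got == expected_max[s$task]))
    fail("per-task phase-duration sums must be 9.5 / 26 / 14 s")
  invisible(battery)
}

#' Maximum battery duration
#'
#' Sums per-trial maximum durations over the scored trials, excluding the
#' untimed attention-getter phases and (by default) the greeting and
#' training introduction: 16 x 9.5 s + 8 x 26 s + 8 x 14 s = 472 s, i.e.
#' about 2 minutes per block and about 8 minutes overall.
#'
#' @param battery A `ja_battery`.
#' @param include_intro Also count the greeting and training trials.
#' @return Duration in ms.
#' @examples
#' battery_max_duration(build_battery(1)) / 60000
#' @export
battery_max_duration <- function(battery, include_intro = FALSE) {
  b <- as_tibble(battery)
  keep <- b$scored | include_intro
  sum(vapply(b$spec[keep], `[[`, 0, "max_duration_ms"))
}

#' @export
print.ja_battery <- function(x, ...) {
  s <- as_tibble(x)[as_tibble(x)$scored, ]
  cat("<ja_battery> ", nrow(s), " scored stimuli in ",
      length(unique(s$block)), " blocks (seed ", attr(x, "seed"), ")\n", sep = "")
  print(battery_composition(x) |>
          tidyr::pivot_wider(names_from = "direction", values_from = "n_trials"))
  cat("max scored duration: ",
      round(battery_max_duration(x) / 60000, 2), " min\n", sep = "")
  invisible(x)
}
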