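#' Read and write gaze-sample streams
#'
#' Gaze streams travel as delimited text with header
#' `t_ms,x_px,y_px,valid` -- the export format of any screen-based eye
#' tracker after minimal reshaping, and the format the simulator writes.
#' Unknown columns are dropped with a warning; malformed rows and
#' non-monotonic timestamps are rejected with the offending line number.
#'
#' @param path File path.
#' @return [read_gaze_stream()] returns a validated gaze tibble.
#' @export
read_gaze_stream <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  .check_problems(df, path)
  extra <- setdiff(names(df), c("t_ms", "x_px", "y_px", "valid"))
  if (length(extra)) {
    warn(paste0("ignoring unknown gaze-stream column(s): ", toString(extra)))
    df <- df[setdiff(names(df), extra)]
  }
  miss <- setdiff(c("t_ms", "x_px", "y_px", "valid"), names(df))
  if (length(miss))
    abort(paste0(path, ": missing gaze-stream column(s): ", toString(miss)))
  df$valid <- as.logical(df$valid)
  if (anyNA(df$valid)) {
    abort(paste0(path, ": unparseable 'valid' value at line ",
                 which(is.na(df$valid))[1] + 1L))
  }
  bad <- !is.finite(df$t_ms)
  if (any(bad))
    abort(paste0(path, ": unparseable timestamp at line ", which(bad)[1] + 1L))
  if (nrow(df) > 1L) {
    d <- diff(df$t_ms)
    if (any(d <= 0)) {
      abort(paste0(path, ": timestamps must be strictly increasing; ",
                   "violation at line ", which(d <= 0)[1] + 2L))
    }
  }
  validate_gaze_stream(df)
}

#' @param samples Gaze tibble to write.
#' @rdname read_gaze_stream
#' @export
write_gaze_stream <- function(samples, path) {
  validate_gaze_stream(samples)
  readr::write_csv(samples[c("t_ms", "x_px", "y_px", "valid")], path,
                   progress = FALSE)
  invisible(path)
}

.check_problems <- function(df, path) {
  pr <- readr::problems(df)
  if (nrow(pr) > 0L) {
    abort(paste0(path, ": malformed row(s) at line(s) ",
                 toString(utils::head(unique(pr$row), 5L) + 1L)))
  }
}

#' Read and write fixation-event tables
#'
#' Pre-detected fixation events use the header
#' `onset_ms,offset_ms,cx_px,cy_px`, so vendor event parsers can feed the
#' engine directly without raw-sample access.
#'
#' @param path File path.
#' @param fixations Fixation tibble.
#' @return [read_fixations()] returns a validated fixation tibble.
#' @export
read_fixations <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  .check_problems(df, path)
  as_fixations(df)
}

#' @rdname read_fixations
#' @export
write_fixations <- function(fixations, path) {
  fixations <- as_fixations(fixations)
  readr::write_csv(fixations[c("onset_ms", "offset_ms", "cx_px", "cy_px")],
                   path, progress = FALSE)
  invisible(path)
}

#' Read a manual-override feed
#'
#' Overrides are researcher-issued phase advances, logged as delimited text
#' `t_ms,note`.
#'
#' @param path File path.
#' @return Tibble with `t_ms` and `note`.
#' @export
read_overrides <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(t_ms = "d", note = "c"))
  .check_problems(df, path)
  if (!"t_ms" %in% names(df)) abort(paste0(path, ": missing column t_ms"))
  if (!"note" %in% names(df)) df$note <- NA_character_
  df[c("t_ms", "note")]
}

#' Read and write transition logs
#'
#' The transition log is JSON-lines: one object per executed phase with
#' fields `trial_id`, `phase`, `cause`, `t_ms`, `latency_ms`, `scheduled`.
#'
#' @param transitions Transition tibble from [run_session()].
#' @param path File path.
#' @return [read_transitions()] returns the transition tibble.
#' @export
write_transitions <- function(transitions, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  jsonlite::stream_out(as.data.frame(transitions), con, verbose = FALSE)
  invisible(path)
}

#' @rdname write_transitions
#' @export
read_transitions <- function(path) {
  con <- file(path, open = "rt")
  on.exit(close(con))
  as_tibble(jsonlite::stream_in(con, verbose = FALSE))
}

#' Write and read battery configurations
#'
#' A battery travels as a declarative YAML document: screen geometry, build
#' seed, and one entry per presented trial (id, task, cue, direction,
#' stimulus set, block, position). Reading reconstructs every trial with
#' [make_trial()] and re-validates all counterbalancing invariants, so a
#' hand-edited configuration violating a constraint is rejected with a
#' named violation.
#'
#' @param battery A `ja_battery`.
#' @param path File path.
#' @param validate Re-check counterbalancing invariants on read (disable to
#'   load deliberately reduced batteries).
#' @return [read_battery_config()] returns a `ja_battery`.
#' @export
write_battery_config <- function(battery, path) {
  stopifnot(inherits(battery, "ja_battery"))
  b <- as_tibble(battery)
  cfg <- list(
    screen = as.integer(attr(battery, "screen") %||% c(1920, 1080)),
    seed = as.integer(attr(battery, "seed") %||% NA_integer_),
    trials = purrr::pmap(
      b[c("position", "block", "trial_id", "task", "cue", "direction",
          "stimulus_set", "scored")],
      function(...) {
        x <- list(...)
        x[!vapply(x, function(v) is.na(v) || is.null(v), TRUE)]
      })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_battery_config
#' @export
read_battery_config <- function(path, validate = TRUE) {
  cfg <- yaml::read_yaml(path)
  for (field in c("screen", "trials")) {
    if (is.null(cfg[[field]]))
      abort(paste0(path, ": battery config missing field '", field, "'"))
  }
  screen <- as.numeric(cfg$screen)
  if (length(screen) != 2L || any(!is.finite(screen)) || any(screen <= 0))
    abort(paste0(path, ": screen must be two positive numbers"))
  rows <- purrr::map(cfg$trials, function(tr) {
    for (field in c("task", "direction", "position")) {
      if (is.null(tr[[field]]))
        abort(paste0(path, ": trial entry missing field '", field, "'"))
    }
    if (!tr$task %in% .ja_tasks)
      abort(paste0(path, ": unknown task '", tr$task, "'"))
    if (!tr$direction %in% .ja_directions)
      abort(paste0(path, ": unknown direction '", tr$direction, "'"))
    tibble(position = as.integer(tr$position),
           block = as.integer(tr$block %||% NA_integer_),
           task = tr$task, cue = tr$cue %||% NA_character_,
           direction = tr$direction,
           stimulus_set = tr$stimulus_set %||% NA_character_)
  })
  tab <- bind_rows(rows) |> arrange(.data$position)
  tab$spec <- purrr::pmap(
    tab[c("task", "direction", "cue", "stimulus_set")],
    function(task, direction, cue, stimulus_set) {
      make_trial(task, direction,
                 cue = if (is.na(cue)) NULL else cue,
                 stimulus_set = if (is.na(stimulus_set)) NULL else stimulus_set,
                 screen = screen)
    })
  tab$trial_id <- purrr::map_chr(tab$spec, "trial_id")
  tab$scored <- purrr::map_lgl(tab$spec, "scored")
  tab <- tab[, c("position", "block", "trial_id", "task", "cue", "direction",
                 "stimulus_set", "scored", "spec")]
  out <- structure(tab, class = c("ja_battery", class(tab)),
                   seed = as.integer(cfg$seed %||% NA_integer_),
                   screen = screen)
  if (validate) validate_battery(out)
  out
}

#' Read a participant-model configuration
#'
#' YAML mapping of [participant_model()] arguments.
#'
#' @param path File path.
#' @return A `ja_participant`.
#' @export
read_participant_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(participant_model))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    abort(paste0(path, ": unknown participant field(s): ", toString(bad)))
  do.call(participant_model, cfg)
}

#' Run the full pipeline on a session bundle
#'
#' Executes validate -> (optionally simulate) -> engine -> score and writes
#' every artifact to `out_dir`: the gaze stream (when simulated), the
#' transition log (`transitions.jsonl`), per-trial results
#' (`trial_results.csv`), the session summary (`session_summary.csv`) and a
#' machine-readable run manifest (`manifest.json`) from which the outputs
#' are reproducible. Deterministic given fixed inputs and seed.
#'
#' @param battery A `ja_battery`, or a path to a battery YAML config.
#' @param out_dir Output directory (created if needed).
#' @param gaze Path to a gaze-stream CSV, or a gaze tibble, or `NULL` to
#'   simulate.
#' @param overrides Path to an override CSV, or a tibble, or `NULL`.
#' @param model A `ja_participant` (or path to its YAML) used when `gaze`
#'   is `NULL`.
#' @param seed Seed for simulation.
#' @inheritParams run_trial
#' @return Invisibly, a list with the summary object and the output paths.
#' @export
run_pipeline <- function(battery, out_dir, gaze = NULL, overrides = NULL,
                         model = NULL, seed = 1L, max_dispersion_px = 60,
                         min_duration_ms = 60, max_gap_ms = 75) {
  if (is.character(battery)) battery <- read_battery_config(battery)
  validate_battery(battery)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(overrides)) overrides <- read_overrides(overrides)
  paths <- list()

  if (is.null(gaze)) {
    if (is.character(model)) model <- read_participant_config(model)
    model <- model %||% participant_model()
    sim <- simulate_session(battery, model, seed = seed)
    samples <- sim$stream
    paths$gaze <- file.path(out_dir, "gaze_stream.csv")
    write_gaze_stream(samples, paths$gaze)
    paths$truth <- file.path(out_dir, "ground_truth.csv")
    readr::write_csv(sim$truth, paths$truth, progress = FALSE)
  } else if (is.character(gaze)) {
    paths$gaze <- gaze
    samples <- read_gaze_stream(gaze)
  } else {
    samples <- validate_gaze_stream(gaze)
  }

  fixations <- detect_fixations(samples, max_dispersion_px, min_duration_ms,
                                max_gap_ms)
  transitions <- run_session(battery, fixations = fixations,
                             overrides = overrides)
  results <- score_session(battery, transitions, fixations)
  summary <- summarize_session(results, transitions)

  paths$transitions <- file.path(out_dir, "transitions.jsonl")
  write_transitions(transitions, paths$transitions)
  paths$results <- file.path(out_dir, "trial_results.csv")
  readr::write_csv(results, paths$results, progress = FALSE)
  paths$summary <- file.path(out_dir, "session_summary.csv")
  readr::write_csv(summary$by_construct, paths$summary, progress = FALSE)
  paths$manifest <- file.path(out_dir, "manifest.json")
  manifest <- list(
    package = "gazejoint",
    version = as.character(utils::packageVersion("gazejoint")),
    seed = as.integer(seed),
    battery_seed = as.integer(attr(battery, "seed") %||% NA_integer_),
    screen = as.numeric(attr(battery, "screen") %||% c(1920, 1080)),
    detector = list(max_dispersion_px = max_dispersion_px,
                    min_duration_ms = min_duration_ms,
                    max_gap_ms = max_gap_ms),
    simulated = is.null(gaze),
    n_trials = nrow(battery),
    outputs = lapply(paths, basename)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(summary = summary, results = results,
                 transitions = transitions, paths = paths))
}
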