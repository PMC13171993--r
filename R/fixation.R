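#' Validate a raw gaze-sample stream
#'
#' A gaze stream is a tibble with columns `t_ms` (session clock, ms,
#' strictly increasing), `x_px`, `y_px` (screen position) and `valid`
#' (FALSE marks blinks / track loss). Positions must be finite on valid
#' samples.
#'
#' @param samples Data frame of gaze samples.
#' @return The stream as a tibble, invisibly checked.
#' @export
validate_gaze_stream <- function(samples) {
  samples <- as_tibble(samples)
  need <- c("t_ms", "x_px", "y_px", "valid")
  miss <- setdiff(need, names(samples))
  if (length(miss)) abort(paste0("gaze stream missing columns: ", toString(miss)))
  if (nrow(samples) > 1L) {
    d <- diff(samples$t_ms)
    if (any(d <= 0)) {
      at <- which(d <= 0)[1] + 1L
      abort(paste0("gaze stream timestamps must be strictly increasing ",
                   "(violated at sample ", at, ")"))
    }
  }
  v <- samples$valid
  if (any(v & (!is.finite(samples$x_px) | !is.finite(samples$y_px))))
    abort("valid gaze samples must have finite x/y positions")
  samples
}

#' Dispersion-threshold (I-DT) fixation detection
#'
#' Parses a raw gaze-sample stream into fixation events with the classic
#' dispersion-threshold algorithm: a fixation is a maximal run of valid
#' samples whose dispersion, `(max x - min x) + (max y - min y)`, stays
#' within `max_dispersion_px`, whose internal gaps between consecutive valid
#' samples do not exceed `max_gap_ms` (short blinks are bridged; longer gaps
#' terminate the fixation), and whose duration reaches `min_duration_ms`.
#'
#' Each sample is taken to represent one sampling interval of gaze, so a
#' fixation's `offset_ms` extends one median inter-sample interval past its
#' last sample; `duration_ms = offset_ms - onset_ms`. Under this convention a
#' stationary scripted fixation of duration `D` sampled at a regular rate is
#' detected with duration exactly `D`.
#'
#' Because dispersion can only grow as a window extends, the greedy maximal
#' window starting at each sample is unique, and the algorithm is equivalent
#' to exhaustively testing all windows against the dispersion/gap/duration
#' predicates and keeping the earliest maximal ones.
#'
#' @param samples Gaze stream (see [validate_gaze_stream()]).
#' @param max_dispersion_px Spatial dispersion window, px. The default 60 px
#'   is about 1.5 degrees of visual angle at a typical 60 cm viewing distance
#'   on a 1920x1080 screen.
#' @param min_duration_ms Minimum fixation duration, ms. Must not exceed
#'   100 ms, the smallest trigger threshold the engine uses.
#' @param max_gap_ms Longest invalid-sample gap bridged inside a fixation, ms.
#' @return Tibble of non-overlapping, time-ordered fixations with columns
#'   `onset_ms`, `offset_ms`, `cx_px`, `cy_px` (centroid of the valid
#'   samples) and `duration_ms`.
#' @examples
#' s <- tibble::tibble(t_ms = seq(0, by = 1000 / 300, length.out = 90),
#'                     x_px = 960, y_px = 540, valid = TRUE)
#' detect_fixations(s)
#' @export
detect_fixations <- function(samples, max_dispersion_px = 60,
                             min_duration_ms = 60, max_gap_ms = 75) {
  stopifnot(max_dispersion_px > 0, min_duration_ms > 0, max_gap_ms > 0)
  if (min_duration_ms > 100)
    abort("min_duration_ms must not exceed 100 ms, the smallest trigger threshold")
  samples <- validate_gaze_stream(samples)
  empty <- tibble(onset_ms = numeric(), offset_ms = numeric(),
                  cx_px = numeric(), cy_px = numeric(), duration_ms = numeric())
  if (nrow(samples) < 2L) return(empty)
  dt <- median(diff(samples$t_ms))

  keep <- samples$valid & is.finite(samples$x_px) & is.finite(samples$y_px)
  t <- samples$t_ms[keep]; x <- samples$x_px[keep]; y <- samples$y_px[keep]
  n <- length(t)
  if (n == 0L) return(empty)

  on <- off <- cx <- cy <- numeric(0)
  i <- 1L
  while (i <= n) {
    xmin <- xmax <- x[i]; ymin <- ymax <- y[i]
    j <- i
    while (j + 1L <= n && t[j + 1L] - t[j] <= max_gap_ms + .ja_eps) {
      nxmin <- min(xmin, x[j + 1L]); nxmax <- max(xmax, x[j + 1L])
      nymin <- min(ymin, y[j + 1L]); nymax <- max(ymax, y[j + 1L])
      if ((nxmax - nxmin) + (nymax - nymin) > max_dispersion_px + .ja_eps) break
      xmin <- nxmin; xmax <- nxmax; ymin <- nymin; ymax <- nymax
      j <- j + 1L
    }
    dur <- t[j] + dt - t[i]
    if (dur >= min_duration_ms - .ja_eps) {
      on <- c(on, t[i]); off <- c(off, t[j] + dt)
      cx <- c(cx, mean(x[i:j])); cy <- c(cy, mean(y[i:j]))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  tibble(onset_ms = on, offset_ms = off, cx_px = cx, cy_px = cy,
         duration_ms = off - on)
}

#' Ingest a pre-detected fixation-event table
#'
#' Alternative front end to [detect_fixations()]: accepts fixation events
#' exported from another system (columns `onset_ms`, `offset_ms`, `cx_px`,
#' `cy_px`), validates ordering and non-overlap, and computes `duration_ms`.
#' Lets the engine run on vendor event files without re-parsing raw samples.
#'
#' @param fixations Data frame of fixation events.
#' @return Validated fixation tibble.
#' @export
as_fixations <- function(fixations) {
  fixations <- as_tibble(fixations)
  need <- c("onset_ms", "offset_ms", "cx_px", "cy_px")
  miss <- setdiff(need, names(fixations))
  if (length(miss)) abort(paste0("fixation table missing columns: ", toString(miss)))
  if (!"duration_ms" %in% names(fixations))
    fixations$duration_ms <- fixations$offset_ms - fixations$onset_ms
  if (any(fixations$duration_ms <= 0))
    abort("fixations must have positive duration (offset_ms > onset_ms)")
  if (nrow(fixations) > 1L) {
    o <- order(fixations$onset_ms)
    fixations <- fixations[o, ]
    if (any(fixations$onset_ms[-1L] < fixations$offset_ms[-nrow(fixations)] - .ja_eps))
      abort("fixations must not overlap in time")
  }
  fixations
}
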