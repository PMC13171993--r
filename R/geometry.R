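#' Screen regions of interest
#'
#' An ROI (region of interest) is a named, half-open axis-aligned rectangle on
#' the presentation screen: a point (x, y) lies inside iff
#' `x0 <= x < x1` and `y0 <= y < y1`. The half-open convention guarantees that
#' abutting ROIs partition their shared boundary, so a gaze point on the seam
#' belongs to exactly one region. Coordinates are pixels, origin at the
#' top-left corner, y increasing downward.
#'
#' @param id Character vector of unique ROI names.
#' @param role Character vector of roles, one of `roi_roles()`.
#' @param x0,y0,x1,y1 Numeric rectangle edges in px (`x0 < x1`, `y0 < y1`).
#' @param screen Screen size in px, `c(width, height)`; all rectangles must
#'   lie within it.
#'
#' @return A tibble with columns `id`, `role`, `x0`, `y0`, `x1`, `y1`.
#' @examples
#' roi_table("Face", "Face", 810, 120, 1110, 420)
#' @export
roi_table <- function(id, role, x0, y0, x1, y1, screen = c(1920, 1080)) {
  rois <- tibble(
    id = as.character(id), role = as.character(role),
    x0 = as.numeric(x0), y0 = as.numeric(y0),
    x1 = as.numeric(x1), y1 = as.numeric(y1)
  )
  validate_rois(rois, screen = screen)
}

#' @rdname roi_table
#' @export
roi_roles <- function() {
  c("AttentionGetter", "Face", "TargetLeft", "TargetRight",
    "TabletLeft", "TabletRight", "ObjectLeft", "ObjectRight", "Other")
}

#' @param rois A tibble as returned by [roi_table()].
#' @rdname roi_table
#' @export
validate_rois <- function(rois, screen = c(1920, 1080)) {
  stopifnot(is.data.frame(rois))
  need <- c("id", "role", "x0", "y0", "x1", "y1")
  miss <- setdiff(need, names(rois))
  if (length(miss)) abort(paste0("ROI table missing columns: ", toString(miss)))
  if (anyDuplicated(rois$id)) abort("ROI ids must be unique within a trial")
  bad_role <- setdiff(rois$role, roi_roles())
  if (length(bad_role)) abort(paste0("unknown ROI role(s): ", toString(bad_role)))
  if (any(rois$x0 >= rois$x1) || any(rois$y0 >= rois$y1))
    abort("ROI rectangles must have x0 < x1 and y0 < y1")
  if (any(rois$x0 < 0) || any(rois$y0 < 0) ||
      any(rois$x1 > screen[1]) || any(rois$y1 > screen[2]))
    abort("ROI rectangles must lie within the screen bounds")
  as_tibble(rois)
}

#' Point-in-ROI test
#'
#' Half-open membership test: true iff `x0 <= x < x1` and `y0 <= y < y1`.
#' Vectorised over `x` and `y`.
#'
#' @param x,y Gaze position in px.
#' @param roi A single ROI: one row of a [roi_table()].
#' @return Logical vector.
#' @examples
#' r <- roi_table("a", "Other", 0, 0, 10, 10)
#' point_in_roi(c(0, 5, 10), c(0, 5, 5), r)
#' @export
point_in_roi <- function(x, y, roi) {
  roi <- as.list(roi[1, , drop = FALSE])
  x >= roi$x0 & x < roi$x1 & y >= roi$y0 & y < roi$y1
}

#' Assign fixations to ROIs by centroid
#'
#' Labels each fixation with the id of the ROI containing its centroid, or
#' `NA` when the centroid falls outside every ROI. Membership is decided by
#' the fixation centroid alone (not a per-sample majority), matching the
#' trigger semantics of "a single fixation on a target ROI". ROIs containing
#' a common centroid are a configuration error.
#'
#' @param fixations Tibble of fixation events (see [detect_fixations()]).
#' @param rois ROI tibble from [roi_table()].
#' @return `fixations` with an added character column `roi`.
#' @export
label_fixations <- function(fixations, rois) {
  fixations <- as_tibble(fixations)
  fixations$roi <- fixation_roi_label(fixations$cx_px, fixations$cy_px, rois)
  fixations
}

#' @param cx,cy Fixation centroid coordinates in px (vectorised).
#' @rdname label_fixations
#' @export
fixation_roi_label <- function(cx, cy, rois) {
  rois <- validate_rois(rois, screen = c(Inf, Inf))
  if (length(cx) == 0L) return(character(0))
  hits <- vapply(seq_len(nrow(rois)), function(i) {
    point_in_roi(cx, cy, rois[i, ])
  }, logical(length(cx)))
  hits <- matrix(hits, nrow = length(cx))
  n_in <- rowSums(hits)
  if (any(n_in > 1L)) {
    abort("overlapping ROIs: a fixation centroid lies inside more than one ROI")
  }
  out <- rep(NA_character_, length(cx))
  has <- n_in == 1L
  out[has] <- rois$id[apply(hits[has, , drop = FALSE], 1L, which)]
  out
}

#' ROI centers
#'
#' Convenience accessor for the geometric center of each ROI, used by the
#' simulator to aim scripted fixations.
#'
#' @inheritParams validate_rois
#' @return Tibble with `id`, `x`, `y`.
#' @export
roi_centers <- function(rois) {
  tibble(id = rois$id, x = (rois$x0 + rois$x1) / 2, y = (rois$y0 + rois$y1) / 2)
}
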