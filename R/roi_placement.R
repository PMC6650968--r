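# Facial ROI model and proportion-based placement.
#
# Eleven facial ROIs are tracked (labels follow the conventional layout):
#   R1 right forehead, R2 left forehead, R3 right periorbital,
#   R4 left periorbital, R5 nose tip, R6 right cheek, R7 left cheek,
#   R8 right perinasal, R9 left perinasal, R10 right chin, R11 left chin.
# Each ROI is a square whose side is a fixed percentage of the head-box
# width, and whose position is anchored to one of the detector boxes (head,
# eyes, nose) via offsets learned from a single expert-annotated frame.

#' ROI region classes and head-width proportions
#'
#' Square ROI side as a fraction of the detected head width: 6.49% nose,
#' 14.28% forehead, 3.24% periorbital, 9.74% cheek, 3.24% perinasal,
#' 5.19% chin.
#' @format Named numeric vector of proportions.
#' @export
roi_proportions <- c(nose = 0.0649, forehead = 0.1428, periorbital = 0.0324,
                     cheek = 0.0974, perinasal = 0.0324, chin = 0.0519)

# region class per facial ROI id 1..11
roi_region_class <- c("forehead", "forehead", "periorbital", "periorbital",
                      "nose", "cheek", "cheek", "perinasal", "perinasal",
                      "chin", "chin")

#' Human-readable ROI labels
#' @format Named character vector keyed by roi id 1..11.
#' @export
roi_labels <- c(`1` = "right forehead", `2` = "left forehead",
                `3` = "right periorbital", `4` = "left periorbital",
                `5` = "nose tip", `6` = "right cheek", `7` = "left cheek",
                `8` = "right perinasal", `9` = "left perinasal",
                `10` = "right chin", `11` = "left chin")

# Which detected box anchors each facial ROI.  The reference table lists
# R1,R2 under both head and eyes and R10,R11 under both head and nose; the
# more specific detector is used as the single anchor (see vignette).
roi_reference_kind <- c("eyes", "eyes", "nose", "nose", "nose",
                        "eyes", "eyes", "eyes", "eyes", "nose", "nose")

#' Construct an ROI box
#'
#' Boxes are `(x, y, w, h)` in 0-based pixel coordinates with half-open
#' extent.  `roi_id` 0 is the head box, 1..11 the facial ROIs; detector
#' boxes use -1 (eyes) and -2 (nose).
#'
#' @param x,y Left-upper corner (may be fractional until final rounding).
#' @param w,h Width and height, at least 1.
#' @param roi_id Integer id.
#' @return An object of class `tf_roi_box`.
#' @export
tf_roi_box <- function(x, y, w, h, roi_id = 0L) {
  if (any(!is.finite(c(x, y, w, h)))) stopf("ROI box fields must be finite")
  if (w < 1 || h < 1) stopf("ROI box must have w, h >= 1 (got %g x %g)", w, h)
  if (!roi_id %in% c(-2:11)) stopf("roi_id must be in {-2..11}")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 w = as.numeric(w), h = as.numeric(h),
                 roi_id = as.integer(roi_id)),
            class = "tf_roi_box")
}

#' @export
print.tf_roi_box <- function(x, ...) {
  cat(sprintf("<tf_roi_box id=%d (%.1f, %.1f) %gx%g>\n",
              x$roi_id, x$x, x$y, x$w, x$h))
  invisible(x)
}

#' Construct an ROI set
#'
#' The head box (roi_id 0, width `W_b`, height `H_b`) plus exactly eleven
#' facial boxes keyed `"1"`..`"11"`.
#'
#' @param head Head [tf_roi_box] with `roi_id = 0`.
#' @param facial List of 11 facial [tf_roi_box], roi_ids 1..11.
#' @param frame_index Frame index `b`.
#' @param annotated Logical; marks expert-annotated reference sets.
#' @return An object of class `tf_roi_set`.
#' @export
tf_roi_set <- function(head, facial, frame_index = 1L, annotated = FALSE) {
  stopifnot(inherits(head, "tf_roi_box"))
  if (head$roi_id != 0L) stopf("head box must have roi_id 0")
  if (length(facial) != 11L) stopf("an ROI set needs exactly 11 facial boxes (got %d)",
                                   length(facial))
  ids <- vapply(facial, function(b) b$roi_id, integer(1))
  if (!setequal(ids, 1:11)) stopf("facial boxes must carry roi_ids 1..11")
  facial <- facial[order(ids)]
  names(facial) <- as.character(1:11)
  structure(list(head = head, facial = facial,
                 frame_index = as.integer(frame_index),
                 annotated = isTRUE(annotated)),
            class = "tf_roi_set")
}

#' @export
print.tf_roi_set <- function(x, ...) {
  cat(sprintf("<tf_roi_set b=%d head %gx%g%s>\n", x$frame_index,
              x$head$w, x$head$h, if (x$annotated) " (annotated)" else ""))
  invisible(x)
}

#' Corner matrix of an ROI set
#' @param rois A [tf_roi_set].
#' @return An 11 x 2 matrix of left-upper corners, rows keyed by roi id.
#' @export
roi_corners <- function(rois) {
  stopifnot(inherits(rois, "tf_roi_set"))
  t(vapply(rois$facial, function(b) c(b$x, b$y), numeric(2)))
}

#' Detector output for one frame
#'
#' The face detector (a Viola-Jones-style cascade on the visual image, or
#' ground truth from the phantom generator) supplies a head box and
#' optionally eyes and nose boxes.  A usable frame needs at least the head.
#'
#' @param head_box Head [tf_roi_box] or `NULL`.
#' @param eyes_box,nose_box Optional [tf_roi_box]es (any roi_id; stored as is).
#' @param frame_index Frame index.
#' @return An object of class `tf_detection_set`.
#' @export
tf_detection_set <- function(head_box = NULL, eyes_box = NULL, nose_box = NULL,
                             frame_index = 1L) {
  for (b in list(head_box, eyes_box, nose_box))
    if (!is.null(b)) stopifnot(inherits(b, "tf_roi_box"))
  structure(list(head_box = head_box, eyes_box = eyes_box,
                 nose_box = nose_box, frame_index = as.integer(frame_index)),
            class = "tf_detection_set")
}

#' ROI square sizes from the head width
#'
#' Side of each region-class square: `round(proportion * head_width)` with
#' half-away-from-zero rounding and a floor of 1 px.
#'
#' @param head_width Detected head-box width in pixels, >= 1.
#' @return Named numeric vector of sides per region class
#'   (nose, forehead, periorbital, cheek, perinasal, chin).
#' @export
roi_sizes_from_head_width <- function(head_width) {
  if (!is.numeric(head_width) || length(head_width) != 1L || head_width < 1)
    stopf("head_width must be a single value >= 1")
  pmax(round_half_away(roi_proportions * unname(head_width)), 1)
}

#' Side of one facial ROI's square from the head width
#' @param k Facial roi id 1..11.
#' @param head_width Head width in pixels.
#' @return Square side in pixels.
#' @export
roi_size_for_k <- function(k, head_width) {
  if (!k %in% 1:11) stopf("k must be in 1..11")
  unname(roi_sizes_from_head_width(head_width)[roi_region_class[k]])
}

resolve_reference_box <- function(detections, kind) {
  box <- switch(kind,
                head = detections$head_box,
                eyes = detections$eyes_box,
                nose = detections$nose_box)
  box
}

#' Learn normalized anchor offsets from the expert annotation
#'
#' For each facial ROI `k`, the offset of the annotated corner from its
#' anchor detector box's corner, normalized by that box's width and height:
#' `offset_k = (C_A^k - corner(ref box)) / (w_ref, h_ref)`.  Re-applying the
#' offsets on another frame's detections places the ROIs subject-
#' specifically, exactly reproducing the annotation when the detections are
#' unchanged.
#'
#' @param annotation An annotated [tf_roi_set] for frame A.
#' @param detections_A The [tf_detection_set] for the same frame (same
#'   camera plane as the annotation).
#' @return A `tf_offset_table`: per-ROI anchor kind and normalized offsets.
#' @export
reference_offsets <- function(annotation, detections_A) {
  stopifnot(inherits(annotation, "tf_roi_set"),
            inherits(detections_A, "tf_detection_set"))
  offs <- matrix(0, nrow = 11L, ncol = 2L,
                 dimnames = list(as.character(1:11), c("ox", "oy")))
  for (k in 1:11) {
    kind <- roi_reference_kind[k]
    ref <- resolve_reference_box(detections_A, kind)
    if (is.null(ref))
      stopf("annotation frame is missing its %s detection (needed for ROI %d)",
            kind, k)
    b <- annotation$facial[[as.character(k)]]
    offs[k, ] <- c((b$x - ref$x) / ref$w, (b$y - ref$y) / ref$h)
  }
  structure(list(offsets = offs, reference_kind = roi_reference_kind),
            class = "tf_offset_table")
}

#' Place the eleven facial ROIs on a frame from its detections
#'
#' Each ROI `k` is anchored at `corner(ref box) + offset_k * (w_ref, h_ref)`
#' using the offsets learned by [reference_offsets()]; its square side comes
#' from [roi_sizes_from_head_width()] applied to the current head width.
#' Missing eyes/nose detections fall back to the previous frame's box
#' (`prev_detections`); a frame without a head detection (and no fallback)
#' is invalid.
#'
#' @param detections_b [tf_detection_set] for the current frame.
#' @param offsets A `tf_offset_table` from [reference_offsets()].
#' @param prev_detections Optional [tf_detection_set] used as fallback for
#'   missing eyes/nose boxes.
#' @return A [tf_roi_set] on the same plane as the detections, or an error
#'   if the frame is unusable.
#' @export
place_rois <- function(detections_b, offsets, prev_detections = NULL) {
  stopifnot(inherits(detections_b, "tf_detection_set"),
            inherits(offsets, "tf_offset_table"))
  head <- detections_b$head_box
  if (is.null(head) && !is.null(prev_detections)) head <- prev_detections$head_box
  if (is.null(head))
    stopf("invalid frame %d: no head detection and no fallback",
          detections_b$frame_index)
  sizes <- roi_sizes_from_head_width(head$w)
  facial <- vector("list", 11L)
  for (k in 1:11) {
    kind <- offsets$reference_kind[k]
    ref <- resolve_reference_box(detections_b, kind)
    if (is.null(ref) && !is.null(prev_detections))
      ref <- resolve_reference_box(prev_detections, kind)
    if (kind == "head" || is.null(ref)) ref <- if (kind == "head") head else ref
    if (is.null(ref))
      stopf("invalid frame %d: missing %s detection for ROI %d and no fallback",
            detections_b$frame_index, kind, k)
    side <- unname(sizes[roi_region_class[k]])
    facial[[k]] <- tf_roi_box(ref$x + offsets$offsets[k, 1] * ref$w,
                              ref$y + offsets$offsets[k, 2] * ref$h,
                              side, side, roi_id = k)
  }
  head0 <- tf_roi_box(head$x, head$y, head$w, head$h, roi_id = 0L)
  tf_roi_set(head0, facial, frame_index = detections_b$frame_index)
}

#' Round an ROI set's corners to integer pixels
#' @param rois A [tf_roi_set].
#' @return The set with all corners rounded half away from zero.
#' @export
round_roi_set <- function(rois) {
  stopifnot(inherits(rois, "tf_roi_set"))
  rnd <- function(b) tf_roi_box(round_half_away(b$x), round_half_away(b$y),
                                b$w, b$h, b$roi_id)
  tf_roi_set(rnd(rois$head), lapply(rois$facial, rnd),
             frame_index = rois$frame_index, annotated = rois$annotated)
}

#' Project every box of an ROI set through a homography
#' @param h A [tf_homography].
#' @param rois A [tf_roi_set].
#' @return The projected [tf_roi_set].
#' @export
project_roi_set <- function(h, rois) {
  stopifnot(inherits(rois, "tf_roi_set"))
  tf_roi_set(project_box(h, rois$head),
             lapply(rois$facial, function(b) project_box(h, b)),
             frame_index = rois$frame_index, annotated = rois$annotated)
}

# ---------------------------------------------------------------------------
# CSV I/O: columns frame_index, roi_id, x, y, w, h.
# roi_id 0 = head, 1..11 facial, -1 = eyes detection, -2 = nose detection.

#' Write ROI sets / detections to CSV
#'
#' @param sets A list of [tf_roi_set] and/or [tf_detection_set].
#' @param path CSV path.
#' @export
write_roi_csv <- function(sets, path) {
  rows <- list()
  add <- function(fi, b) {
    if (!is.null(b))
      rows[[length(rows) + 1L]] <<- data.frame(frame_index = fi, roi_id = b$roi_id,
                                               x = b$x, y = b$y, w = b$w, h = b$h)
  }
  for (s in sets) {
    if (inherits(s, "tf_roi_set")) {
      add(s$frame_index, s$head)
      for (b in s$facial) add(s$frame_index, b)
    } else if (inherits(s, "tf_detection_set")) {
      add(s$frame_index, s$head_box)
      if (!is.null(s$eyes_box))
        add(s$frame_index, tf_roi_box(s$eyes_box$x, s$eyes_box$y,
                                      s$eyes_box$w, s$eyes_box$h, -1L))
      if (!is.null(s$nose_box))
        add(s$frame_index, tf_roi_box(s$nose_box$x, s$nose_box$y,
                                      s$nose_box$w, s$nose_box$h, -2L))
    } else stopf("write_roi_csv handles tf_roi_set / tf_detection_set")
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read ROI sets and detections from CSV
#'
#' @param path CSV with columns frame_index, roi_id, x, y, w, h.
#' @param annotated Mark returned ROI sets as expert-annotated.
#' @return A list with `roi_sets` (per frame, when all 12 boxes present) and
#'   `detections` (per frame).
#' @export
read_roi_csv <- function(path, annotated = FALSE) {
  tab <- utils::read.csv(path)
  need <- c("frame_index", "roi_id", "x", "y", "w", "h")
  if (!all(need %in% names(tab)))
    stopf("ROI CSV must have columns %s", paste(need, collapse = ", "))
  out_sets <- list(); out_dets <- list()
  for (fi in sort(unique(tab$frame_index))) {
    sub <- tab[tab$frame_index == fi, ]
    box_for <- function(id) {
      r <- sub[sub$roi_id == id, ]
      if (nrow(r) == 0L) return(NULL)
      r <- r[1, ]
      tf_roi_box(r$x, r$y, r$w, r$h, roi_id = max(id, 0L))
    }
    head <- box_for(0L)
    eyes <- box_for(-1L); nose <- box_for(-2L)
    if (!is.null(head) || !is.null(eyes) || !is.null(nose))
      out_dets[[as.character(fi)]] <-
        tf_detection_set(head_box = head,
                         eyes_box = if (is.null(eyes)) NULL else
                           tf_roi_box(eyes$x, eyes$y, eyes$w, eyes$h, -1L),
                         nose_box = if (is.null(nose)) NULL else
                           tf_roi_box(nose$x, nose$y, nose$w, nose$h, -2L),
                         frame_index = fi)
    if (!is.null(head) && all(1:11 %in% sub$roi_id)) {
      facial <- lapply(1:11, function(k) {
        r <- sub[sub$roi_id == k, ][1, ]
        tf_roi_box(r$x, r$y, r$w, r$h, roi_id = k)
      })
      out_sets[[as.character(fi)]] <-
        tf_roi_set(head, facial, frame_index = fi, annotated = annotated)
    }
  }
  list(roi_sets = out_sets, detections = out_dets)
}
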