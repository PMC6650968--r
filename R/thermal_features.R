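# Thermal appearance features.
#
# Per ROI patch (m x n grid of 8-bit brightness), seven static statistics:
#   c1 mean of all pixels
#   c2 variance of all pixels, divisor (m*n)-1
#   c3 median of all pixels
#   c4 mean over rows of the per-row variance (divisor n-1)
#   c5 mean of the per-row medians
#   c6 mean over columns of the per-column variance (divisor m-1)
#   c7 mean of the per-column medians
# plus seven temporal differences c8..c14 = current c1..c7 minus the same
# statistics on the previous frame (zeros on the first frame).  Eleven ROIs
# x 14 features = 154 features per frame.  Median of an even-count sample is
# the mean of the two middle values; degenerate divisors (1x1 patch,
# single-pixel rows/columns) yield variance 0.

#' Crop an ROI patch out of a thermal frame
#'
#' The half-open box is intersected with the frame; an ROI entirely outside
#' the frame is an error.
#'
#' @param frame A thermal [tf_frame].
#' @param box A [tf_roi_box] (integer corners expected).
#' @return An object of class `tf_roi_patch` (fields `pixels`, `roi_id`,
#'   `frame_index`).
#' @export
crop_patch <- function(frame, box) {
  stopifnot(inherits(frame, "tf_frame"), inherits(box, "tf_roi_box"))
  x0 <- max(0, round_half_away(box$x)); y0 <- max(0, round_half_away(box$y))
  x1 <- min(frame$width, round_half_away(box$x + box$w))
  y1 <- min(frame$height, round_half_away(box$y + box$h))
  if (x1 <= x0 || y1 <= y0)
    stopf("ROI %d lies outside frame %d", box$roi_id, frame$frame_index)
  px <- frame$pixels[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  structure(list(pixels = px, roi_id = box$roi_id,
                 frame_index = frame$frame_index),
            class = "tf_roi_patch")
}

var0 <- function(x) if (length(x) < 2L) 0 else stats::var(x)

#' Static features of an ROI patch
#'
#' The seven whole-patch / per-row / per-column statistics c1..c7 described
#' above.
#'
#' @param patch A `tf_roi_patch`, or a plain numeric matrix.
#' @return Numeric length-7 vector named c1..c7.
#' @export
static_features <- function(patch) {
  px <- if (inherits(patch, "tf_roi_patch")) patch$pixels else patch
  if (!is.matrix(px) || length(px) == 0L) stopf("patch must be a non-empty matrix")
  if (any(!is.finite(px))) stopf("patch pixels must be finite")
  c(c1 = mean(px),
    c2 = var0(as.vector(px)),
    c3 = stats::median(px),
    c4 = mean(apply(px, 1L, var0)),
    c5 = mean(apply(px, 1L, stats::median)),
    c6 = mean(apply(px, 2L, var0)),
    c7 = mean(apply(px, 2L, stats::median)))
}

#' Temporal feature differences between consecutive frames
#'
#' `c(8..14) = current c(1..7) - previous c(1..7)`; all zeros when there is
#' no previous frame (first-frame convention, keeps the vector length fixed).
#'
#' @param curr Length-7 static features of the current frame's patch.
#' @param prev Length-7 static features of the previous frame's patch, or
#'   `NULL` on the first frame.
#' @return Numeric length-7 vector named c8..c14.
#' @export
temporal_differences <- function(curr, prev = NULL) {
  if (length(curr) != 7L) stopf("curr must have length 7")
  d <- if (is.null(prev)) rep(0, 7L) else {
    if (length(prev) != 7L) stopf("prev must have length 7")
    as.numeric(curr) - as.numeric(prev)
  }
  names(d) <- paste0("c", 8:14)
  d
}

#' Full feature vector of one frame
#'
#' Concatenates the 14 features of each of the 11 ROI patches in fixed
#' `(k, c)` order — k major, c minor — giving names `f{k}_{c}` and length
#' 154.
#'
#' @param patches List of exactly 11 `tf_roi_patch` (roi_ids 1..11).
#' @param prev_statics Optional list of 11 length-7 static feature vectors
#'   from the previous frame (keyed "1".."11"); `NULL` on the first frame.
#' @return A list with `values` (named length-154 numeric), `statics` (the
#'   per-ROI static features, to pass as `prev_statics` for the next frame)
#'   and `frame_index`.
#' @export
frame_feature_vector <- function(patches, prev_statics = NULL) {
  if (length(patches) != 11L)
    stopf("a frame feature vector needs exactly 11 ROI patches (got %d)",
          length(patches))
  ids <- vapply(patches, function(p) p$roi_id, integer(1))
  if (!setequal(ids, 1:11)) stopf("patches must carry roi_ids 1..11")
  patches <- patches[order(ids)]
  statics <- lapply(patches, static_features)
  names(statics) <- as.character(1:11)
  values <- numeric(0)
  for (k in 1:11) {
    s <- statics[[as.character(k)]]
    p <- if (is.null(prev_statics)) NULL else prev_statics[[as.character(k)]]
    block <- c(s, temporal_differences(s, p))
    names(block) <- paste0("f", k, "_", 1:14)
    values <- c(values, block)
  }
  stopifnot(length(values) == 154L)
  list(values = values, statics = statics,
       frame_index = patches[[1]]$frame_index)
}

#' Feature table for a sequence of frames
#'
#' Crops each frame's ROIs, computes the 154-feature vector per frame with
#' consecutive-frame differences, and stacks the rows.
#'
#' @param frames List of thermal [tf_frame].
#' @param roi_sets List of [tf_roi_set], one per frame (same order).
#' @param labels Optional per-frame labels (emotion class).
#' @return A data frame: `frame_index`, `f1_1` .. `f11_14`, and `label` if
#'   given.
#' @export
sequence_feature_table <- function(frames, roi_sets, labels = NULL) {
  if (length(frames) != length(roi_sets))
    stopf("frames and roi_sets must have equal length")
  prev <- NULL
  rows <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    patches <- lapply(roi_sets[[i]]$facial, function(b) crop_patch(frames[[i]], b))
    fv <- frame_feature_vector(patches, prev)
    prev <- fv$statics
    rows[[i]] <- c(frame_index = frames[[i]]$frame_index, fv$values)
  }
  tab <- as.data.frame(do.call(rbind, rows))
  if (!is.null(labels)) {
    if (length(labels) != length(frames)) stopf("labels length mismatch")
    tab$label <- labels
  }
  tab
}

#' Write / read a feature table CSV
#'
#' Layout: `frame_index`, 154 columns `f{k}_{c}` (k = 1..11, c = 1..14),
#' optional `label` — compatible with published labeled feature databases in
#' the same layout, so those can be loaded directly.
#'
#' @param tab Feature data frame.
#' @param path CSV path.
#' @export
write_feature_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @return `read_feature_csv`: a list with `features` (n x 154 matrix),
#'   `labels` (factor or NULL) and `frame_index`.
#' @export
read_feature_csv <- function(path) {
  tab <- utils::read.csv(path)
  fcols <- paste0("f", rep(1:11, each = 14), "_", rep(1:14, times = 11))
  if (!all(fcols %in% names(tab)))
    stopf("feature CSV lacks the 154 f{k}_{c} columns")
  list(features = as.matrix(tab[, fcols]),
       labels = if ("label" %in% names(tab)) factor(tab$label) else NULL,
       frame_index = if ("frame_index" %in% names(tab)) tab$frame_index else
         seq_len(nrow(tab)))
}
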