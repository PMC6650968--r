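# Error-probability ROI relocation.
#
# Automatic placement (cascade detection on the visual image followed by
# homography projection) drifts relative to expert criteria.  To correct it
# frame-by-frame against a single expert-annotated reference frame A, each
# ROI's left-upper corner is scored by a softmax of negative absolute
# deviations in head-normalized coordinates, separately in x and y:
#
#   pbx[k] = exp(-|Cbx^k/Wb - CAx^k/WA|) / sum_i exp(-|Cbx^i/Wb - CAx^i/WA|)
#   pby[k] = exp(-|Cby^k/Hb - CAy^k/HA|) / sum_i exp(-|Cby^i/Hb - CAy^i/HA|)
#   pb[k]  = min(pbx[k], pby[k])
#
# The best-scoring ROI (highest pb: lowest location error) is then used as
# the anchor from which every other ROI is re-derived using the annotated
# inter-ROI offsets rescaled by the head-size ratios:
#
#   C'bx[k] = Cbx[ref] + (CAx[k] - CAx[ref]) * Wb/WA
#   C'by[k] = Cby[ref] + (CAy[k] - CAy[ref]) * Hb/HA

#' Location probabilities of the eleven ROIs against the expert annotation
#'
#' Softmax (over the 11 ROIs) of negative absolute deviations between the
#' current and annotated left-upper corners in head-normalized coordinates,
#' computed separately per axis; the combined score per ROI is the minimum
#' of its two axis probabilities.  Values near `1/11` on both axes mean the
#' placement agrees with the expert everywhere.
#'
#' @param rois_b [tf_roi_set] for frame b (thermal plane).
#' @param annotation Annotated [tf_roi_set] for frame A (same plane).
#' @return An object of class `tf_location_probs` with fields `pbx`, `pby`,
#'   `pb` (length-11 numeric, named "1".."11") and `frame_index`.
#' @export
location_probabilities <- function(rois_b, annotation) {
  stopifnot(inherits(rois_b, "tf_roi_set"), inherits(annotation, "tf_roi_set"))
  Wb <- rois_b$head$w; Hb <- rois_b$head$h
  WA <- annotation$head$w; HA <- annotation$head$h
  if (Wb <= 0 || Hb <= 0 || WA <= 0 || HA <= 0)
    stopf("head boxes must have positive width and height")
  cb <- roi_corners(rois_b); ca <- roi_corners(annotation)
  dx <- abs(cb[, 1] / Wb - ca[, 1] / WA)
  dy <- abs(cb[, 2] / Hb - ca[, 2] / HA)
  ex <- exp(-dx); ey <- exp(-dy)
  pbx <- ex / sum(ex); pby <- ey / sum(ey)
  pb <- pmin(pbx, pby)
  names(pbx) <- names(pby) <- names(pb) <- as.character(1:11)
  structure(list(pbx = pbx, pby = pby, pb = pb,
                 frame_index = rois_b$frame_index),
            class = "tf_location_probs")
}

#' @export
print.tf_location_probs <- function(x, ...) {
  cat(sprintf("<tf_location_probs b=%d best=R%d pb=%.4f>\n", x$frame_index,
              select_reference_roi(x), max(x$pb)))
  invisible(x)
}

#' Select the reference (anchor) ROI from location probabilities
#'
#' Default mode `"best"` returns the argmax of `pb` — the ROI whose placement
#' agrees most with the expert (lowest location error).  Mode `"worst"`
#' returns the argmin, provided because the source description of the method
#' is self-contradictory on this point (see vignette); `"best"` is the
#' reading under which relocation provably recovers the ground truth.
#' Ties break toward the smallest ROI index.
#'
#' @param probs A `tf_location_probs`.
#' @param mode `"best"` (argmax of pb, default) or `"worst"` (argmin).
#' @return The selected roi index k* in 1..11.
#' @export
select_reference_roi <- function(probs, mode = c("best", "worst")) {
  stopifnot(inherits(probs, "tf_location_probs"))
  mode <- match.arg(mode)
  pb <- probs$pb
  k <- if (mode == "best") which.max(pb) else which.min(pb)
  as.integer(names(pb)[k])
}

#' Relocate all ROIs from the selected reference ROI
#'
#' Every ROI's corner is re-derived from the reference ROI's current corner
#' plus the annotated inter-ROI offset rescaled by the head-size ratios
#' `Wb/WA` and `Hb/HA`.  Sizes are unchanged; the reference ROI maps to
#' itself; corners are rounded to integer pixels last (disable with
#' `round = FALSE` for sub-pixel analysis).  The operation is idempotent:
#' relocating an already-relocated set with the same reference is a no-op.
#'
#' @param rois_b [tf_roi_set] for frame b.
#' @param k_ref Reference roi index in 1..11.
#' @param annotation Annotated [tf_roi_set].
#' @param round Round corners to integer pixels (default TRUE).
#' @return The relocated [tf_roi_set].
#' @export
relocate_rois <- function(rois_b, k_ref, annotation, round = TRUE) {
  stopifnot(inherits(rois_b, "tf_roi_set"), inherits(annotation, "tf_roi_set"))
  if (!is_count(k_ref) || !k_ref %in% 1:11)
    stopf("k_ref must be an ROI index in 1..11")
  sx <- rois_b$head$w / annotation$head$w
  sy <- rois_b$head$h / annotation$head$h
  ref_b <- rois_b$facial[[as.character(k_ref)]]
  ref_a <- annotation$facial[[as.character(k_ref)]]
  # rounding the anchor first makes rounded relocation idempotent
  ref_x <- if (round) round_half_away(ref_b$x) else ref_b$x
  ref_y <- if (round) round_half_away(ref_b$y) else ref_b$y
  facial <- lapply(1:11, function(k) {
    b <- rois_b$facial[[as.character(k)]]
    a <- annotation$facial[[as.character(k)]]
    x <- ref_x + (a$x - ref_a$x) * sx
    y <- ref_y + (a$y - ref_a$y) * sy
    if (round) { x <- round_half_away(x); y <- round_half_away(y) }
    tf_roi_box(x, y, b$w, b$h, roi_id = k)
  })
  tf_roi_set(rois_b$head, facial, frame_index = rois_b$frame_index)
}

#' Score, select and relocate in one step
#'
#' @inheritParams relocate_rois
#' @inheritParams select_reference_roi
#' @param annotation Annotated [tf_roi_set].
#' @return A list with `rois` (relocated set), `probs`, and `k_ref`.
#' @export
relocate_frame <- function(rois_b, annotation, mode = "best", round = TRUE) {
  probs <- location_probabilities(rois_b, annotation)
  k_ref <- select_reference_roi(probs, mode)
  list(rois = relocate_rois(rois_b, k_ref, annotation, round = round),
       probs = probs, k_ref = k_ref)
}

#' Per-frame relocation report
#'
#' One row per ROI: the axis and combined probabilities, whether the ROI was
#' the selected anchor, and the corner before and after relocation.
#'
#' @param rois_before [tf_roi_set] prior to relocation.
#' @param relocated Result of [relocate_frame()] on that set.
#' @return A data frame with columns `frame_index, roi_id, pbx, pby, pb,
#'   selected, x_before, y_before, x_after, y_after`.
#' @export
relocation_report <- function(rois_before, relocated) {
  cb <- roi_corners(rois_before); ca <- roi_corners(relocated$rois)
  data.frame(frame_index = rois_before$frame_index, roi_id = 1:11,
             pbx = unname(relocated$probs$pbx),
             pby = unname(relocated$probs$pby),
             pb = unname(relocated$probs$pb),
             selected = 1:11 == relocated$k_ref,
             x_before = cb[, 1], y_before = cb[, 2],
             x_after = ca[, 1], y_after = ca[, 2])
}
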