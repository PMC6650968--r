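test_that("ROI sizes follow the head-width proportions", {
  s100 <- roi_sizes_from_head_width(100)
  expect_equal(unname(s100[c("nose", "forehead", "periorbital",
                             "cheek", "perinasal", "chin")]),
               c(6, 14, 3, 10, 3, 5))
  expect_equal(unname(roi_sizes_from_head_width(1)), rep(1, 6))  # floor guard
  # doubling the width doubles the pre-rounding sizes: nose round(12.98)=13
  expect_equal(unname(roi_sizes_from_head_width(200)["nose"]), 13)
  expect_error(roi_sizes_from_head_width(0), ">= 1")

  # monotone non-decreasing in head width
  widths <- seq(10, 400, by = 7)
  sizes <- t(vapply(widths, roi_sizes_from_head_width, numeric(6)))
  expect_true(all(apply(sizes, 2, function(col) all(diff(col) >= 0))))

  expect_equal(roi_size_for_k(5, 100), 6)   # nose
  expect_equal(roi_size_for_k(1, 100), 14)  # forehead
})

test_that("reference offsets are normalized by the anchor box", {
  ann <- test_annotation()
  det <- tf_detection_set(
    head_box = tf_roi_box(0, 0, 100, 120, 0L),
    eyes_box = tf_roi_box(20, 30, 100, 50, -1L),
    nose_box = tf_roi_box(40, 55, 30, 25, -2L), frame_index = 1L)
  offs <- reference_offsets(ann, det)
  expect_equal(dim(offs$offsets), c(11L, 2L))

  # an ROI whose corner equals its anchor corner has offset (0, 0):
  # R1 anchors to the eyes box
  ann2 <- ann
  ann2$facial[["1"]] <- tf_roi_box(20, 30, 5, 5, 1L)
  offs2 <- reference_offsets(ann2, det)
  expect_equal(unname(offs2$offsets["1", ]), c(0, 0))

  # an ROI at the anchor-box center of a 100x50 box has offset (0.5, 0.5)
  ann3 <- ann
  ann3$facial[["1"]] <- tf_roi_box(20 + 50, 30 + 25, 5, 5, 1L)
  offs3 <- reference_offsets(ann3, det)
  expect_equal(unname(offs3$offsets["1", ]), c(0.5, 0.5))

  expect_error(reference_offsets(ann, tf_detection_set(det$head_box)),
               "missing")
})

test_that("place_rois round-trips, translates and scales with detections", {
  ann <- test_annotation()
  det_A <- tf_detection_set(
    head_box = tf_roi_box(0, 0, 100, 120, 0L),
    eyes_box = tf_roi_box(20, 30, 60, 18, -1L),
    nose_box = tf_roi_box(42, 55, 18, 20, -2L), frame_index = 1L)
  offs <- reference_offsets(ann, det_A)

  # identity: same detections reproduce the annotated corners exactly
  placed <- place_rois(det_A, offs)
  expect_rois_equal(placed, ann)

  # translation by (10, 0) translates every ROI by (10, 0)
  shift <- function(b, dx, dy) tf_roi_box(b$x + dx, b$y + dy, b$w, b$h, b$roi_id)
  det_t <- tf_detection_set(shift(det_A$head_box, 10, 0),
                            shift(det_A$eyes_box, 10, 0),
                            shift(det_A$nose_box, 10, 0), frame_index = 2L)
  placed_t <- place_rois(det_t, offs)
  expect_equal(roi_corners(placed_t), roi_corners(placed) +
                 matrix(rep(c(10, 0), each = 11), ncol = 2),
               ignore_attr = TRUE)

  # scaling 2x about the origin scales corners 2x and sizes 2x (+- rounding)
  scale2 <- function(b) tf_roi_box(2 * b$x, 2 * b$y, 2 * b$w, 2 * b$h, b$roi_id)
  det_s <- tf_detection_set(scale2(det_A$head_box), scale2(det_A$eyes_box),
                            scale2(det_A$nose_box), frame_index = 3L)
  placed_s <- place_rois(det_s, offs)
  expect_equal(roi_corners(placed_s), 2 * roi_corners(placed),
               tolerance = 1e-9, ignore_attr = TRUE)
  for (k in 1:11) {
    w1 <- placed$facial[[k]]$w; w2 <- placed_s$facial[[k]]$w
    expect_lte(abs(w2 - 2 * w1), 1)  # rounding slack
  }
  expect_length(placed_s$facial, 11L)
})

test_that("missing detections use the previous frame or invalidate the frame", {
  ann <- test_annotation()
  det_A <- tf_detection_set(
    head_box = tf_roi_box(0, 0, 100, 120, 0L),
    eyes_box = tf_roi_box(20, 30, 60, 18, -1L),
    nose_box = tf_roi_box(42, 55, 18, 20, -2L), frame_index = 1L)
  offs <- reference_offsets(ann, det_A)

  det_b <- tf_detection_set(head_box = det_A$head_box, frame_index = 2L)
  # no eyes/nose and no previous frame: invalid
  expect_error(place_rois(det_b, offs), "invalid frame")
  # with the previous frame's boxes the frame is usable and identical here
  expect_rois_equal(place_rois(det_b, offs, prev_detections = det_A),
                    place_rois(det_A, offs))
  # no head anywhere: invalid
  expect_error(place_rois(tf_detection_set(frame_index = 3L), offs),
               "no head detection")
})

test_that("ROI CSV round-trips sets and detections", {
  dir <- withr::local_tempdir()
  ann <- test_annotation()
  det <- tf_detection_set(
    head_box = tf_roi_box(0, 0, 100, 120, 0L),
    eyes_box = tf_roi_box(20, 30, 60, 18, -1L),
    nose_box = tf_roi_box(42, 55, 18, 20, -2L), frame_index = 1L)
  write_roi_csv(list(ann, det), file.path(dir, "r.csv"))
  got <- read_roi_csv(file.path(dir, "r.csv"), annotated = TRUE)
  expect_length(got$roi_sets, 1L)
  expect_rois_equal(got$roi_sets[["1"]], ann)
  expect_true(got$roi_sets[["1"]]$annotated)
  expect_equal(got$detections[["1"]]$eyes_box$x, 20)
  expect_equal(got$detections[["1"]]$nose_box$w, 18)
})

test_that("ROI set constructor enforces the 11-box contract", {
  boxes <- lapply(1:10, function(k) tf_roi_box(k, k, 5, 5, k))
  expect_error(tf_roi_set(tf_roi_box(0, 0, 50, 50, 0L), boxes), "11 facial")
  dup <- c(boxes, list(tf_roi_box(1, 1, 5, 5, 10L)))
  expect_error(tf_roi_set(tf_roi_box(0, 0, 50, 50, 0L), dup), "1..11")
  expect_error(tf_roi_box(0, 0, 0, 5), "w, h >= 1")
})
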