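test_that("equal normalized placement gives the uniform distribution", {
  ann <- test_annotation()
  p <- location_probabilities(ann, ann)
  expect_equal(unname(p$pbx), rep(1 / 11, 11))
  expect_equal(unname(p$pby), rep(1 / 11, 11))
  expect_equal(unname(p$pb), rep(1 / 11, 11))
})

test_that("probability vectors are normalized softmaxes of the deviations", {
  ann <- test_annotation()
  set.seed(13)
  for (i in 1:20) {
    corners <- roi_corners(ann) + matrix(rnorm(22, 0, 8), ncol = 2)
    rois <- make_roi_set(corners, head = c(0, 0, 90, 130), frame_index = 2L)
    p <- location_probabilities(rois, ann)
    expect_equal(sum(p$pbx), 1, tolerance = 1e-12)
    expect_equal(sum(p$pby), 1, tolerance = 1e-12)
    expect_true(all(p$pbx > 0 & p$pbx < 1))
    expect_true(all(p$pb <= p$pbx & p$pb <= p$pby))
    orc <- oracle_location_probs(corners, roi_corners(ann), 90, 130, 100, 120)
    expect_equal(unname(p$pbx), unname(orc$pbx), tolerance = 1e-12)
    expect_equal(unname(p$pby), unname(orc$pby), tolerance = 1e-12)
    expect_equal(unname(p$pb), unname(orc$pb), tolerance = 1e-12)
  }
})

test_that("single-displacement case matches the closed form", {
  # only ROI 1 displaced by 0.5 in normalized x:
  # pbx[1] = e^-0.5/(e^-0.5 + 10), others 1/(e^-0.5 + 10)
  ann <- test_annotation()
  corners <- roi_corners(ann)
  corners[1, 1] <- corners[1, 1] + 0.5 * ann$head$w
  rois <- make_roi_set(corners, head = c(0, 0, 100, 120), frame_index = 2L)
  p <- location_probabilities(rois, ann)
  denom <- exp(-0.5) + 10
  expect_equal(unname(p$pbx[1]), exp(-0.5) / denom, tolerance = 1e-12)
  expect_equal(unname(p$pbx[-1]), rep(1 / denom, 10), tolerance = 1e-12)
  expect_equal(unname(p$pby), rep(1 / 11, 11), tolerance = 1e-12)
})

test_that("reference selection uses argmax of pb with smallest-index ties", {
  ann <- test_annotation()
  expect_equal(select_reference_roi(location_probabilities(ann, ann)), 1L)

  # exactly one ROI at its annotated normalized position wins
  set.seed(3)
  for (kstar in c(2L, 7L, 11L)) {
    corners <- roi_corners(ann)
    jit <- matrix(runif(22, 3, 10) * sample(c(-1, 1), 22, TRUE), ncol = 2)
    jit[kstar, ] <- 0
    rois <- make_roi_set(corners + jit, head = c(0, 0, 100, 120))
    p <- location_probabilities(rois, ann)
    expect_equal(select_reference_roi(p), kstar)
    expect_equal(select_reference_roi(p, mode = "worst"),
                 as.integer(which.min(p$pb)))
  }

  # min rule: an ROI displaced only in y loses to a fully correct ROI
  corners <- roi_corners(ann)
  corners[, 1] <- corners[, 1] + 5; corners[, 2] <- corners[, 2] + 5
  corners[2, ] <- roi_corners(ann)[2, ] + c(0, 8)  # perfect in x, off in y
  corners[4, ] <- roi_corners(ann)[4, ]            # fully correct
  p <- location_probabilities(make_roi_set(corners, head = c(0, 0, 100, 120)), ann)
  expect_equal(select_reference_roi(p), 4L)
})

test_that("relocation reproduces the annotated geometry", {
  ann <- test_annotation()
  set.seed(21)
  corners <- roi_corners(ann) + matrix(rnorm(22, 0, 6), ncol = 2)
  rois <- make_roi_set(corners, head = c(0, 0, 100, 120), frame_index = 4L)

  # the reference ROI maps to itself
  rel <- relocate_rois(rois, 3L, ann, round = FALSE)
  expect_equal(roi_corners(rel)[3, ], corners[3, ], ignore_attr = TRUE)

  # same head size and a correctly placed reference: exact annotation
  corners2 <- roi_corners(ann) + 5
  corners2[6, ] <- roi_corners(ann)[6, ]
  rois2 <- make_roi_set(corners2, head = c(0, 0, 100, 120))
  rel2 <- relocate_rois(rois2, 6L, ann, round = FALSE)
  expect_rois_equal(rel2, ann)

  # head twice the annotated size: inter-ROI offsets exactly doubled
  rois3 <- make_roi_set(2 * roi_corners(ann), head = c(0, 0, 200, 240))
  rel3 <- relocate_rois(rois3, 1L, ann, round = FALSE)
  d_ann <- sweep(roi_corners(ann), 2, roi_corners(ann)[1, ])
  d_rel <- sweep(roi_corners(rel3), 2, roi_corners(rel3)[1, ])
  expect_equal(d_rel, 2 * d_ann, ignore_attr = TRUE)

  # sizes unchanged, idempotence after rounding
  rel_r <- relocate_rois(rois, 3L, ann)
  expect_equal(vapply(rel_r$facial, function(b) b$w, numeric(1)),
               vapply(rois$facial, function(b) b$w, numeric(1)))
  expect_rois_equal(relocate_rois(rel_r, 3L, ann), rel_r)

  expect_error(relocate_rois(rois, 12, ann), "1..11")
})

test_that("exact recovery: one unperturbed ROI anchors full recovery", {
  ann <- test_annotation()
  set.seed(77)
  for (i in 1:25) {
    kstar <- sample(1:11, 1)
    # current head is smaller than the annotated one; ground truth is the
    # annotation at the same normalized coordinates in the new head frame
    head_b <- c(0, 0, 80, 100)
    sx <- head_b[3] / ann$head$w; sy <- head_b[4] / ann$head$h
    gt <- cbind(roi_corners(ann)[, 1] * sx, roi_corners(ann)[, 2] * sy)
    jit <- matrix(runif(22, 2, 9) * sample(c(-1, 1), 22, TRUE), ncol = 2)
    jit[kstar, ] <- 0
    rois <- make_roi_set(gt + jit, head = head_b, frame_index = i)
    res <- relocate_frame(rois, ann, round = FALSE)
    expect_equal(res$k_ref, kstar)
    expect_equal(roi_corners(res$rois), gt, tolerance = 1e-9,
                 ignore_attr = TRUE)
    # after rounding, within 1 px
    res_r <- relocate_frame(rois, ann)
    expect_lte(max(abs(roi_corners(res_r$rois) - gt)), 1)
  }
})

test_that("relocation reduces mean corner error over jittered frames", {
  ann <- test_annotation()
  set.seed(99)
  err_raw <- err_rel <- numeric(0)
  for (i in 1:120) {
    gt <- roi_corners(ann)
    rois <- make_roi_set(gt + matrix(rnorm(22, 0, 4), ncol = 2),
                         head = c(0, 0, 100, 120), frame_index = i)
    res <- relocate_frame(rois, ann, round = FALSE)
    err_raw <- c(err_raw, sqrt(rowSums((roi_corners(rois) - gt)^2)))
    err_rel <- c(err_rel, sqrt(rowSums((roi_corners(res$rois) - gt)^2)))
  }
  expect_lte(mean(err_rel), mean(err_raw))
})

test_that("relocation report carries probabilities and corners", {
  ann <- test_annotation()
  set.seed(2)
  rois <- make_roi_set(roi_corners(ann) + matrix(rnorm(22, 0, 3), ncol = 2),
                       head = c(0, 0, 100, 120), frame_index = 6L)
  res <- relocate_frame(rois, ann)
  rep <- relocation_report(rois, res)
  expect_equal(nrow(rep), 11L)
  expect_equal(sum(rep$selected), 1L)
  expect_equal(rep$roi_id[rep$selected], res$k_ref)
  expect_equal(rep$pb, unname(res$probs$pb))
})
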