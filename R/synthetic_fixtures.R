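# Synthetic face-phantom generator.
#
# Renders paired visual/thermal sequences with full ground truth so every
# pipeline stage is testable without external recordings.  The thermal face
# is a smooth warm ellipse (so ROI statistics are non-degenerate) with
# per-ROI brightness offsets depending on the emotion class, plus a fixed-
# pattern noise field identical in every frame and optional salt-and-pepper
# noise.  The visual frame is a geometrically consistent RGB rendering at
# twice the thermal resolution; the true visual->thermal homography is the
# 0.5x scaling map.  Detections are the true head/eyes/nose boxes plus
# i.i.d. Gaussian corner jitter, truncated to keep boxes inside the frame.

#' Phantom configuration
#'
#' Defaults emulate the acquisition conditions of a seated child filmed by
#' a rigidly mounted visual + thermal pair: 2 fps, thermal 160x120 and
#' visual 320x240 (half-scale geometry of the real 384x288 sensor keeps
#' tests fast), slow sinusoidal head sway of a few pixels with a gentle
#' scale oscillation, detector jitter of ~2 px, fixed-pattern noise up to
#' 6 brightness levels and a 0.2% salt-and-pepper rate.
#'
#' @param thermal_size `(w, h)` of thermal frames.
#' @param visual_scale Visual-over-thermal resolution ratio (homography).
#' @param head_center,head_axes Ellipse center and semi-axes, thermal px.
#' @param roi_layout 11 x 2 matrix of ROI corner positions as fractions of
#'   the head box (defaults to a plausible facial layout).
#' @param class_offsets 5 x 11 matrix of per-class, per-ROI thermal
#'   brightness offsets (rows in [emotion_classes] order).
#' @param sway_amp `(x, y)` amplitude of the sinusoidal head sway, px.
#' @param sway_period Sway period in frames.
#' @param scale_amp Relative amplitude of the head scale oscillation.
#' @param jitter_sd Detector corner jitter standard deviation, px.
#' @param fpn_amplitude Fixed-pattern noise amplitude (uniform \[0, a\]).
#' @param salt_pepper_rate Fraction of pixels hit by salt-and-pepper noise.
#' @param n_frames Number of frame pairs.
#' @param rate_hz Frame rate (timestamps).
#' @param labels Per-frame class labels (codes 1..5 or names), recycled.
#' @param seed Random seed; sequences are deterministic given the seed.
#' @return A `tf_phantom_config`.
#' @export
phantom_config <- function(thermal_size = c(160L, 120L),
                           visual_scale = 2,
                           head_center = c(80, 56),
                           head_axes = c(26, 36),
                           roi_layout = default_roi_layout(),
                           class_offsets = default_class_offsets(),
                           sway_amp = c(5, 3),
                           sway_period = 20,
                           scale_amp = 0.04,
                           jitter_sd = 2,
                           fpn_amplitude = 6,
                           salt_pepper_rate = 0.002,
                           n_frames = 30L,
                           rate_hz = 2,
                           labels = "happiness",
                           seed = 1L) {
  if (any(c(jitter_sd, fpn_amplitude, salt_pepper_rate) < 0))
    stopf("rates and amplitudes must be >= 0")
  if (!all(dim(roi_layout) == c(11L, 2L)) ||
      min(roi_layout) < 0 || max(roi_layout) > 1)
    stopf("roi_layout must be 11 x 2 with fractions in [0, 1]")
  if (!all(dim(class_offsets) == c(5L, 11L)))
    stopf("class_offsets must be 5 x 11")
  if (head_axes[1] <= 0 || head_axes[2] <= 0) stopf("invalid head geometry")
  if (head_center[1] - head_axes[1] < 0 ||
      head_center[1] + head_axes[1] > thermal_size[1] ||
      head_center[2] - head_axes[2] < 0 ||
      head_center[2] + head_axes[2] > thermal_size[2])
    stopf("head ellipse must fit inside the thermal frame")
  lab <- labels
  if (is.character(lab)) lab <- match(lab, emotion_classes)
  if (any(is.na(lab)) || any(!lab %in% 1:5)) stopf("labels must be 1..5 or class names")
  lab <- rep_len(as.integer(lab), n_frames)
  structure(list(thermal_size = as.integer(thermal_size),
                 visual_scale = visual_scale, head_center = head_center,
                 head_axes = head_axes, roi_layout = roi_layout,
                 class_offsets = class_offsets, sway_amp = sway_amp,
                 sway_period = sway_period, scale_amp = scale_amp,
                 jitter_sd = jitter_sd, fpn_amplitude = fpn_amplitude,
                 salt_pepper_rate = salt_pepper_rate,
                 n_frames = as.integer(n_frames), rate_hz = rate_hz,
                 labels = lab, seed = as.integer(seed)),
            class = "tf_phantom_config")
}

#' Default ground-truth ROI corner layout (fractions of the head box)
#'
#' Rows are roi ids 1..11; columns are (fx, fy): the ROI's left-upper
#' corner at `head_corner + (fx * W, fy * H)`.  Right-side ROIs (subject's
#' right) sit on the image left.
#' @return 11 x 2 numeric matrix.
#' @export
default_roi_layout <- function() {
  m <- rbind(c(0.22, 0.06),  # R1 right forehead
             c(0.64, 0.06),  # R2 left forehead
             c(0.26, 0.30),  # R3 right periorbital
             c(0.70, 0.30),  # R4 left periorbital
             c(0.47, 0.46),  # R5 nose tip
             c(0.12, 0.52),  # R6 right cheek
             c(0.78, 0.52),  # R7 left cheek
             c(0.36, 0.62),  # R8 right perinasal
             c(0.60, 0.62),  # R9 left perinasal
             c(0.30, 0.84),  # R10 right chin
             c(0.62, 0.84))  # R11 left chin
  dimnames(m) <- list(as.character(1:11), c("fx", "fy"))
  m
}

#' Default per-class thermal offsets per ROI (brightness levels)
#'
#' Signed offsets added inside each ROI box, emulating the directional skin
#' temperature changes reported for emotional arousal: nose-tip cooling
#' under fear/disgust, periorbital warming under fear/surprise, cheek and
#' forehead warming under happiness, mild forehead cooling under sadness.
#' @return 5 x 11 matrix, rows in [emotion_classes] order.
#' @export
default_class_offsets <- function() {
  m <- matrix(0, 5, 11, dimnames = list(emotion_classes, as.character(1:11)))
  m["disgust", ] <- c(0, 0, 4, 4, -8, 0, 0, 6, 6, 0, 0)
  m["fear", ] <- c(2, 2, 8, 8, -15, 0, 0, 4, 4, 0, 0)
  m["happiness", ] <- c(5, 5, 3, 3, 2, 10, 10, 3, 3, 4, 4)
  m["sadness", ] <- c(-6, -6, -2, -2, -3, -2, -2, 0, 0, -2, -2)
  m["surprise", ] <- c(8, 8, 8, 8, 0, 3, 3, 2, 2, 0, 0)
  m
}

# head box and detector boxes (thermal plane, fractional coordinates) for a
# given ellipse center/axes
head_box_from_ellipse <- function(center, axes) {
  c(x = unname(center[1] - axes[1]), y = unname(center[2] - axes[2]),
    w = unname(2 * axes[1]), h = unname(2 * axes[2]))
}

detector_boxes_from_head <- function(hb) {
  list(head = hb,
       eyes = c(x = unname(hb["x"] + 0.15 * hb["w"]),
                y = unname(hb["y"] + 0.26 * hb["h"]),
                w = unname(0.70 * hb["w"]), h = unname(0.14 * hb["h"])),
       nose = c(x = unname(hb["x"] + 0.38 * hb["w"]),
                y = unname(hb["y"] + 0.42 * hb["h"]),
                w = unname(0.24 * hb["w"]), h = unname(0.20 * hb["h"])))
}

roi_set_from_head <- function(hb, layout, frame_index, annotated = FALSE) {
  sizes <- roi_sizes_from_head_width(hb["w"])
  facial <- lapply(1:11, function(k) {
    side <- unname(sizes[roi_region_class[k]])
    tf_roi_box(unname(hb["x"] + layout[k, 1] * hb["w"]),
               unname(hb["y"] + layout[k, 2] * hb["h"]),
               side, side, roi_id = k)
  })
  head <- tf_roi_box(unname(hb["x"]), unname(hb["y"]),
                     unname(hb["w"]), unname(hb["h"]), roi_id = 0L)
  tf_roi_set(head, facial, frame_index = frame_index, annotated = annotated)
}

#' Generate a paired visual/thermal phantom sequence with ground truth
#'
#' @param config A [phantom_config()].
#' @return A list:
#' \describe{
#'   \item{thermal, visual}{lists of [tf_frame]}
#'   \item{truth}{`rois` (true thermal-plane [tf_roi_set] per frame),
#'     `rois_visual`, `detections` (true visual-plane [tf_detection_set]),
#'     `detections_jittered` (with corner jitter), `labels`,
#'     `noise_reference` (the fixed-pattern field actually added),
#'     `homography` (true visual->thermal map), `annotation` /
#'     `annotation_visual` (frame-1 truth, marked annotated)}
#' }
#' @export
generate_sequence <- function(config) {
  stopifnot(inherits(config, "tf_phantom_config"))
  set.seed(config$seed)
  tw <- config$thermal_size[1]; th <- config$thermal_size[2]
  vs <- config$visual_scale
  vw <- as.integer(round(tw * vs)); vh <- as.integer(round(th * vs))
  fpn <- matrix(stats::runif(tw * th, 0, config$fpn_amplitude), nrow = th)
  H_vt <- tf_homography(diag(c(1 / vs, 1 / vs, 1)))
  xg <- matrix(rep(0:(tw - 1), each = th), nrow = th)
  yg <- matrix(rep(0:(th - 1), times = tw), nrow = th)
  thermal <- visual <- vector("list", config$n_frames)
  rois <- rois_v <- dets <- dets_j <- vector("list", config$n_frames)
  for (b in seq_len(config$n_frames)) {
    phase <- 2 * pi * (b - 1) / config$sway_period
    ctr <- config$head_center + c(config$sway_amp[1] * sin(phase),
                                  config$sway_amp[2] * cos(phase))
    axes <- config$head_axes * (1 + config$scale_amp * sin(phase / 2))
    hb <- head_box_from_ellipse(ctr, axes)
    truth_rois <- roi_set_from_head(hb, config$roi_layout, b, annotated = (b == 1L))
    # thermal rendering: warm smooth ellipse on a cool background
    r2 <- ((xg - ctr[1]) / axes[1])^2 + ((yg - ctr[2]) / axes[2])^2
    img <- 40 + 150 * exp(-1.2 * r2)
    off <- config$class_offsets[config$labels[b], ]
    for (k in 1:11) {
      bx <- truth_rois$facial[[k]]
      x0 <- round_half_away(bx$x); y0 <- round_half_away(bx$y)
      xs <- clamp((x0 + 1):(x0 + bx$w), 1, tw)
      ys <- clamp((y0 + 1):(y0 + bx$h), 1, th)
      img[ys, xs] <- img[ys, xs] + off[k]
    }
    clean <- clamp(img, 0, 255)
    noisy <- clamp(clean + fpn, 0, 255)
    if (config$salt_pepper_rate > 0) {
      npix <- tw * th
      hit <- which(stats::runif(npix) < config$salt_pepper_rate)
      if (length(hit)) noisy[hit] <- ifelse(stats::runif(length(hit)) < 0.5, 0, 255)
    }
    ts <- (b - 1) / config$rate_hz
    thermal[[b]] <- tf_frame(round_half_away(noisy), ts, "thermal", b)
    # visual rendering: skin-tone ellipse + dark eye/nose blobs, 2x scale
    vxg <- matrix(rep(0:(vw - 1), each = vh), nrow = vh)
    vyg <- matrix(rep(0:(vh - 1), times = vw), nrow = vh)
    vr2 <- ((vxg - ctr[1] * vs) / (axes[1] * vs))^2 +
           ((vyg - ctr[2] * vs) / (axes[2] * vs))^2
    face <- vr2 <= 1
    vis <- array(30, dim = c(vh, vw, 3))
    vis[, , 1][face] <- 210; vis[, , 2][face] <- 170; vis[, , 3][face] <- 140
    db <- detector_boxes_from_head(hb)
    for (part in c("eyes", "nose")) {
      pb <- db[[part]] * vs
      xs <- clamp(round_half_away(pb["x"] + 1):round_half_away(pb["x"] + pb["w"]), 1, vw)
      ys <- clamp(round_half_away(pb["y"] + 1):round_half_away(pb["y"] + pb["h"]), 1, vh)
      for (ch in 1:3) vis[ys, xs, ch] <- vis[ys, xs, ch] * 0.4
    }
    visual[[b]] <- tf_frame(clamp(vis, 0, 255), ts, "visual", b)
    # ground truth on both planes; detections on the visual plane
    rois[[b]] <- truth_rois
    rois_v[[b]] <- scale_roi_set(truth_rois, vs)
    mk_box <- function(v, id) tf_roi_box(unname(v["x"]) * vs, unname(v["y"]) * vs,
                                         unname(v["w"]) * vs, unname(v["h"]) * vs, id)
    dets[[b]] <- tf_detection_set(mk_box(db$head, 0L), mk_box(db$eyes, -1L),
                                  mk_box(db$nose, -2L), frame_index = b)
    jit <- function(box) {
      if (config$jitter_sd == 0) return(box)
      dx <- stats::rnorm(1, 0, config$jitter_sd)
      dy <- stats::rnorm(1, 0, config$jitter_sd)
      x <- clamp(box$x + dx, 0, vw - box$w)
      y <- clamp(box$y + dy, 0, vh - box$h)
      tf_roi_box(x, y, box$w, box$h, box$roi_id)
    }
    dets_j[[b]] <- tf_detection_set(jit(dets[[b]]$head_box),
                                    jit(dets[[b]]$eyes_box),
                                    jit(dets[[b]]$nose_box), frame_index = b)
  }
  list(thermal = thermal, visual = visual,
       truth = list(rois = rois, rois_visual = rois_v,
                    detections = dets, detections_jittered = dets_j,
                    labels = config$labels,
                    noise_reference = tf_noise_reference(fpn),
                    homography = H_vt,
                    annotation = rois[[1]],
                    annotation_visual = rois_v[[1]]))
}

# scale an ROI set about the origin (used to express thermal-plane truth on
# the visual plane, whose geometry is an exact scaling in the phantom)
scale_roi_set <- function(rois, s) {
  sc <- function(b) tf_roi_box(b$x * s, b$y * s, b$w * s, b$h * s, b$roi_id)
  tf_roi_set(sc(rois$head), lapply(rois$facial, sc),
             frame_index = rois$frame_index, annotated = rois$annotated)
}

#' Generate a labeled synthetic feature dataset
#'
#' Class-conditional Gaussian feature vectors: unit-variance isotropic noise
#' around class means placed at `separation` standard deviations from the
#' origin along independent random directions, one per class.  Balanced
#' labels 1..n_classes; deterministic given the seed.
#'
#' @param n_per_class Samples per class (>= 2).
#' @param n_classes Number of classes (default 5).
#' @param separation Class-mean distance from the origin in sd units.
#' @param d Feature dimension (default 154).
#' @param seed Random seed.
#' @return A list with `features` (n x d matrix) and `labels` (integer
#'   codes 1..n_classes).
#' @export
generate_feature_dataset <- function(n_per_class, n_classes = 5L,
                                     separation = 5, d = 154L, seed = 1L) {
  if (!is_count(n_per_class) || n_per_class < 2L)
    stopf("n_per_class must be an integer >= 2")
  set.seed(seed)
  means <- matrix(0, n_classes, d)
  for (cl in seq_len(n_classes)) {
    u <- stats::rnorm(d); u <- u / sqrt(sum(u^2))
    means[cl, ] <- separation * u
  }
  n <- n_per_class * n_classes
  X <- matrix(0, n, d)
  y <- integer(n)
  row <- 1L
  for (cl in seq_len(n_classes)) {
    for (i in seq_len(n_per_class)) {
      X[row, ] <- means[cl, ] + stats::rnorm(d)
      y[row] <- cl
      row <- row + 1L
    }
  }
  list(features = X, labels = y)
}
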