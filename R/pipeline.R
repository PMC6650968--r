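# End-to-end orchestration.
#
# Stage order follows the system design: calibrate -> preprocess (noise
# subtraction + median filter) -> place ROIs on the visual plane -> project
# to the thermal plane -> relocate against the expert annotation -> extract
# features -> (optionally) train/evaluate the classifier.

#' Pipeline configuration
#'
#' @param pairing_rate_hz Stream pairing rate (default 2 fps).
#' @param median_kernel Median filter window (odd, default 3).
#' @param relocation_mode `"best"` (argmax reference, default), `"worst"`,
#'   or `"off"` to skip relocation.
#' @param pca_components PCA dimensionality (default 60).
#' @param classifier Classifier kind (default `"lda_full"`).
#' @param kfold,runs Cross-validation folds (3) and repeats (10).
#' @param seed Root seed for all randomness.
#' @param invalid_frame_threshold Fraction of invalid frames tolerated
#'   before [run_pipeline()] errors (default 0.5).
#' @return A `tf_pipeline_config`.
#' @export
pipeline_config <- function(pairing_rate_hz = 2, median_kernel = 3L,
                            relocation_mode = c("best", "worst", "off"),
                            pca_components = 60L, classifier = "lda_full",
                            kfold = 3L, runs = 10L, seed = 1L,
                            invalid_frame_threshold = 0.5) {
  relocation_mode <- match.arg(relocation_mode)
  structure(list(pairing_rate_hz = pairing_rate_hz,
                 median_kernel = as.integer(median_kernel),
                 relocation_mode = relocation_mode,
                 pca_components = as.integer(pca_components),
                 classifier = classifier, kfold = as.integer(kfold),
                 runs = as.integer(runs), seed = as.integer(seed),
                 invalid_frame_threshold = invalid_frame_threshold),
            class = "tf_pipeline_config")
}

#' Run the ROI localization + feature extraction pipeline
#'
#' Takes in-memory inputs (frames, detections, annotation, calibration) and
#' runs: noise subtraction, median filtering, offset learning from the
#' annotation (mapped to the visual plane through the inverse homography),
#' per-frame ROI placement on the visual plane, homography projection to
#' the thermal plane, error-probability relocation, and feature extraction.
#'
#' @param thermal_frames,visual_frames Paired frame lists (same length,
#'   index-aligned). `visual_frames` may be `NULL` (only detections are
#'   needed).
#' @param detections List of per-frame visual-plane [tf_detection_set].
#' @param annotation Expert thermal-plane [tf_roi_set] for the reference
#'   frame.
#' @param homography Visual->thermal [tf_homography].
#' @param noise_reference Optional [tf_noise_reference].
#' @param config A [pipeline_config()].
#' @param labels Optional per-frame class labels for the feature table.
#' @param truth_rois Optional list of ground-truth thermal [tf_roi_set] for
#'   placement evaluation.
#' @return A list: `features` (data frame), `rois_raw`, `rois_relocated`,
#'   `relocation_reports` (data frame), `placement` (placement comparison
#'   data frame, when `truth_rois` given), `invalid_frames` (indices),
#'   `stage_counts` (named vector).
#' @export
run_pipeline <- function(thermal_frames, visual_frames = NULL, detections,
                         annotation, homography,
                         noise_reference = NULL,
                         config = pipeline_config(),
                         labels = NULL, truth_rois = NULL) {
  stopifnot(inherits(config, "tf_pipeline_config"),
            inherits(annotation, "tf_roi_set"),
            inherits(homography, "tf_homography"))
  n <- length(thermal_frames)
  if (length(detections) != n)
    stopf("detections (%d) and thermal frames (%d) must align",
          length(detections), n)
  # preprocess
  frames <- lapply(thermal_frames, function(f) {
    if (!is.null(noise_reference)) f <- subtract_noise_reference(f, noise_reference)
    median_filter(f, config$median_kernel)
  })
  # learn anchor offsets on the visual plane
  h_inv <- invert_homography(homography)
  annotation_visual <- project_roi_set(h_inv, annotation)
  ref_frame <- annotation$frame_index
  det_A <- detections[[ref_frame]]
  offsets <- reference_offsets(annotation_visual, det_A)
  rois_raw <- rois_rel <- vector("list", n)
  reports <- list()
  invalid <- integer(0)
  prev_det <- NULL
  for (b in seq_len(n)) {
    placed <- tryCatch(place_rois(detections[[b]], offsets, prev_det),
                       error = function(e) NULL)
    if (is.null(placed)) { invalid <- c(invalid, b); next }
    prev_det <- detections[[b]]
    thermal_set <- project_roi_set(homography, placed)
    rois_raw[[b]] <- thermal_set
    if (config$relocation_mode == "off") {
      rois_rel[[b]] <- thermal_set
    } else {
      rel <- relocate_frame(thermal_set, annotation, mode = config$relocation_mode)
      rois_rel[[b]] <- rel$rois
      reports[[length(reports) + 1L]] <- relocation_report(thermal_set, rel)
    }
  }
  if (length(invalid) > config$invalid_frame_threshold * n)
    stopf("%d of %d frames invalid (threshold %.0f%%)", length(invalid), n,
          100 * config$invalid_frame_threshold)
  ok <- setdiff(seq_len(n), invalid)
  features <- sequence_feature_table(frames[ok], rois_rel[ok],
                                     labels = if (is.null(labels)) NULL else labels[ok])
  placement <- NULL
  if (!is.null(truth_rois)) {
    cmp <- list()
    for (b in ok) {
      cmp[[length(cmp) + 1L]] <- compare_placements(rois_raw[[b]], truth_rois[[b]], "raw")
      if (config$relocation_mode != "off")
        cmp[[length(cmp) + 1L]] <-
          compare_placements(rois_rel[[b]], truth_rois[[b]], "relocated")
    }
    placement <- do.call(rbind, cmp)
  }
  list(features = features,
       rois_raw = rois_raw, rois_relocated = rois_rel,
       relocation_reports = if (length(reports)) do.call(rbind, reports) else NULL,
       placement = placement, invalid_frames = invalid,
       stage_counts = c(frames = n, valid = length(ok),
                        invalid = length(invalid)))
}

#' Command-line interface
#'
#' Subcommands: `simulate` (write a phantom sequence + ground truth),
#' `calibrate` (estimate a homography from a correspondence CSV),
#' `extract` (run the pipeline on a simulated sequence and write the
#' feature CSV), `train` (cross-validate a classifier on a feature CSV).
#' Invoke from `Rscript -e 'thermoface::tf_cli()' ...` or a wrapper script.
#'
#' @param args Character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Invisibly, the subcommand's result.
#' @export
tf_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: tf_cli <simulate|calibrate|extract|train> [--key value ...]\n")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  get_opt <- function(name, default = NULL) {
    if (!is.null(opts[[name]])) opts[[name]] else default
  }
  seed <- as.integer(get_opt("seed", 1))
  switch(cmd,
    simulate = {
      out <- get_opt("out", ".")
      cfg <- phantom_config(n_frames = as.integer(get_opt("frames", 30)),
                            seed = seed)
      seq <- generate_sequence(cfg)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      side <- list()
      for (b in seq_along(seq$thermal)) {
        tp <- sprintf("thermal_%03d.pgm", b); vp <- sprintf("visual_%03d.ppm", b)
        write_frame(seq$thermal[[b]], file.path(out, tp))
        write_frame(seq$visual[[b]], file.path(out, vp))
        side[[b]] <- data.frame(frame_index = b,
                                timestamp = seq$thermal[[b]]$timestamp,
                                file = tp)
      }
      utils::write.csv(do.call(rbind, side), file.path(out, "thermal_index.csv"),
                       row.names = FALSE)
      write_roi_csv(seq$truth$rois, file.path(out, "truth_rois.csv"))
      write_roi_csv(seq$truth$detections_jittered, file.path(out, "detections.csv"))
      write_homography(seq$truth$homography, file.path(out, "homography.json"))
      message(sprintf("wrote %d frame pairs to %s", length(seq$thermal), out))
      invisible(seq)
    },
    calibrate = {
      corr <- read_correspondences(get_opt("correspondences"))
      h <- estimate_homography(corr)
      write_homography(h, get_opt("out", "homography.json"))
      invisible(h)
    },
    extract = {
      cfg <- phantom_config(n_frames = as.integer(get_opt("frames", 30)),
                            seed = seed)
      seq <- generate_sequence(cfg)
      res <- run_pipeline(seq$thermal, seq$visual,
                          seq$truth$detections_jittered,
                          seq$truth$annotation, seq$truth$homography,
                          seq$truth$noise_reference,
                          config = pipeline_config(seed = seed),
                          labels = seq$truth$labels,
                          truth_rois = seq$truth$rois)
      write_feature_csv(res$features, get_opt("out", "features.csv"))
      message(sprintf("stage counts: %s",
                      paste(names(res$stage_counts), res$stage_counts,
                            sep = "=", collapse = " ")))
      invisible(res)
    },
    train = {
      feats <- read_feature_csv(get_opt("features"))
      if (is.null(feats$labels)) stopf("feature CSV has no label column")
      cv <- cross_validate(feats$features, feats$labels,
                           kind = get_opt("classifier", "lda_full"),
                           q = as.integer(get_opt("components", 60)),
                           k = as.integer(get_opt("kfold", 3)),
                           runs = as.integer(get_opt("runs", 10)),
                           seed = seed)
      print(cv)
      out <- get_opt("out")
      if (!is.null(out)) {
        jsonlite::write_json(list(acc = cv$acc, acc_se = cv$acc_se,
                                  kappa = cv$kappa, kappa_se = cv$kappa_se,
                                  tpr = cv$tpr, fpr = cv$fpr),
                             out, auto_unbox = TRUE, digits = NA)
      }
      invisible(cv)
    },
    stopf("unknown subcommand '%s'", cmd))
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stopf("unexpected argument '%s'", a)
    key <- substring(a, 3L)
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stopf("option --%s needs a value", key)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}
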