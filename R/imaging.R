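# Frame model and thermal pre-processing.
#
# Thermal frames are 8-bit grayscale: brightness 0-255 where brighter means
# warmer (no radiometric calibration to degrees; the pipeline operates on
# brightness only).  Visual frames are 8-bit RGB.  All pixel coordinates in
# the package are 0-based, x rightward, y downward; boxes are (x, y, w, h)
# with half-open extent [x, x+w) x [y, y+h).

#' Construct a frame
#'
#' A frame wraps a pixel grid with a timestamp, a frame index and a kind.
#' Thermal frames are single-channel matrices (rows = y, columns = x);
#' visual frames are h x w x 3 arrays.  All intensities must lie in
#' \[0, 255\].
#'
#' @param pixels Numeric matrix (thermal) or h x w x 3 array (visual).
#' @param timestamp Acquisition time in seconds.
#' @param kind `"thermal"` or `"visual"`.
#' @param frame_index Integer index `b` of the frame within its stream.
#' @return An object of class `tf_frame`.
#' @export
tf_frame <- function(pixels, timestamp = 0, kind = c("thermal", "visual"),
                     frame_index = 1L) {
  kind <- match.arg(kind)
  if (kind == "thermal") {
    if (!is.matrix(pixels)) stopf("thermal frames must be single-channel matrices")
  } else {
    if (!(is.array(pixels) && length(dim(pixels)) == 3L && dim(pixels)[3] == 3L))
      stopf("visual frames must be h x w x 3 arrays")
  }
  if (any(!is.finite(pixels))) stopf("frame pixels must be finite")
  if (min(pixels) < 0 || max(pixels) > 255)
    stopf("frame intensities must lie in [0, 255]")
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  if (h < 1 || w < 1) stopf("frame dimensions must be >= 1")
  structure(
    list(pixels = pixels, width = w, height = h,
         timestamp = as.numeric(timestamp), kind = kind,
         frame_index = as.integer(frame_index)),
    class = "tf_frame")
}

#' @export
print.tf_frame <- function(x, ...) {
  cat(sprintf("<tf_frame %s %dx%d b=%d t=%.3fs>\n",
              x$kind, x$width, x$height, x$frame_index, x$timestamp))
  invisible(x)
}

#' Fixed-pattern noise reference
#'
#' Uncooled infrared sensors carry a static per-pixel offset (fixed-pattern
#' noise).  Recording a uniform-temperature target yields a reference frame
#' holding that offset, which is subtracted from every subsequent thermal
#' frame.
#'
#' @param pixels Numeric matrix of per-pixel offsets.
#' @return An object of class `tf_noise_reference`.
#' @export
tf_noise_reference <- function(pixels) {
  if (!is.matrix(pixels) || any(!is.finite(pixels)))
    stopf("noise reference must be a finite numeric matrix")
  structure(list(pixels = pixels,
                 width = ncol(pixels), height = nrow(pixels)),
            class = "tf_noise_reference")
}

#' Subtract the fixed-pattern noise reference from a thermal frame
#'
#' Pixel-to-pixel subtraction, clipped back into \[0, 255\] so the 8-bit
#' contract is preserved (negative differences clip to 0).
#'
#' @param frame A thermal [tf_frame].
#' @param ref A [tf_noise_reference] with matching dimensions.
#' @return The corrected thermal frame.
#' @export
subtract_noise_reference <- function(frame, ref) {
  stopifnot(inherits(frame, "tf_frame"), inherits(ref, "tf_noise_reference"))
  if (frame$kind != "thermal") stopf("noise subtraction applies to thermal frames")
  if (frame$width != ref$width || frame$height != ref$height)
    stopf("dimension mismatch: frame %dx%d vs reference %dx%d",
          frame$width, frame$height, ref$width, ref$height)
  out <- clamp(frame$pixels - ref$pixels, 0, 255)
  tf_frame(out, frame$timestamp, "thermal", frame$frame_index)
}

#' Median-filter a thermal frame
#'
#' Each pixel is replaced by the median of its `kernel` x `kernel`
#' neighbourhood; borders are handled by edge replication so ROIs near the
#' frame edge are not shrunk.  Removes salt-and-pepper noise.
#'
#' @param frame A thermal [tf_frame].
#' @param kernel Odd window size, default 3.
#' @return The filtered frame.
#' @export
median_filter <- function(frame, kernel = 3L) {
  stopifnot(inherits(frame, "tf_frame"))
  if (!is_count(kernel) || kernel < 1L || kernel %% 2L == 0L)
    stopf("kernel must be an odd integer >= 1")
  if (kernel == 1L) return(frame)
  px <- frame$pixels
  h <- nrow(px); w <- ncol(px)
  r <- (kernel - 1L) %/% 2L
  # replicate-pad, then collect the k^2 shifted copies column-wise
  pad <- px[clamp(seq_len(h + 2 * r) - r, 1L, h),
            clamp(seq_len(w + 2 * r) - r, 1L, w), drop = FALSE]
  k2 <- kernel * kernel
  stack <- matrix(0, nrow = h * w, ncol = k2)
  idx <- 1L
  for (dy in 0:(kernel - 1L)) {
    for (dx in 0:(kernel - 1L)) {
      stack[, idx] <- as.vector(pad[dy + seq_len(h), dx + seq_len(w)])
      idx <- idx + 1L
    }
  }
  med <- apply(stack, 1L, stats::median)
  tf_frame(matrix(med, nrow = h, ncol = w), frame$timestamp, "thermal",
           frame$frame_index)
}

#' Pair visual and thermal streams at a fixed rate
#'
#' The two cameras free-run at different native rates; downstream processing
#' wants synchronized pairs at `rate_hz` (default 2 fps).  A tick grid at
#' `1/rate_hz` spacing is laid over the overlapping time span; each tick is
#' matched to the nearest-timestamp frame in each stream, and ticks whose
#' best match in either stream is further than half a period away are
#' dropped.
#'
#' @param visual_frames,thermal_frames Lists of [tf_frame] with monotone
#'   timestamps.
#' @param rate_hz Pairing rate in Hz.
#' @return A list of `tf_frame_pair` objects, sorted by `pair_timestamp`.
#' @export
pair_streams <- function(visual_frames, thermal_frames, rate_hz = 2) {
  if (length(visual_frames) == 0L || length(thermal_frames) == 0L)
    stopf("both streams must be non-empty")
  if (!is.numeric(rate_hz) || rate_hz <= 0) stopf("rate_hz must be positive")
  vt <- vapply(visual_frames, function(f) f$timestamp, numeric(1))
  tt <- vapply(thermal_frames, function(f) f$timestamp, numeric(1))
  if (is.unsorted(vt) || is.unsorted(tt))
    stopf("stream timestamps must be monotone non-decreasing")
  period <- 1 / rate_hz
  t0 <- max(vt[1], tt[1]); t1 <- min(vt[length(vt)], tt[length(tt)])
  if (t1 < t0) return(list())
  ticks <- seq(t0, t1, by = period)
  pairs <- list()
  for (tk in ticks) {
    iv <- which.min(abs(vt - tk))
    it <- which.min(abs(tt - tk))
    if (abs(vt[iv] - tk) > period / 2 || abs(tt[it] - tk) > period / 2) next
    pairs[[length(pairs) + 1L]] <- structure(
      list(visual = visual_frames[[iv]], thermal = thermal_frames[[it]],
           pair_timestamp = tk),
      class = "tf_frame_pair")
  }
  pairs
}

# ---------------------------------------------------------------------------
# NetPBM I/O.  ASCII PGM (P2) for 8-bit gray thermal frames, ASCII PPM (P3)
# for RGB visual frames; plain-text formats so fixtures stay diffable.

#' Write a frame as ASCII PGM/PPM
#'
#' Thermal frames are written as plain PGM (magic `P2`), visual frames as
#' plain PPM (`P3`), both with maxval 255.  Pixels are rounded to integers.
#'
#' @param frame A [tf_frame].
#' @param path Output file path.
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "tf_frame"))
  con <- file(path, "w"); on.exit(close(con))
  if (frame$kind == "thermal") {
    vals <- as.integer(round_half_away(t(frame$pixels)))  # row-major scan
    writeLines(c("P2", sprintf("%d %d", frame$width, frame$height), "255"), con)
  } else {
    px <- round_half_away(frame$pixels)
    # interleave R,G,B per pixel in row-major order
    vals <- integer(frame$width * frame$height * 3L)
    n <- frame$width * frame$height
    for (ch in 1:3) {
      vals[seq(ch, by = 3L, length.out = n)] <- as.integer(t(px[, , ch]))
    }
    writeLines(c("P3", sprintf("%d %d", frame$width, frame$height), "255"), con)
  }
  writeLines(paste(vals, collapse = " "), con)
  invisible(path)
}

#' Read a frame from ASCII PGM/PPM
#'
#' @param path Path to a plain PGM (P2) or PPM (P3) file.
#' @param timestamp,frame_index Metadata attached to the returned frame
#'   (NetPBM carries none).
#' @return A [tf_frame]; kind is inferred from the magic number.
#' @export
read_frame <- function(path, timestamp = 0, frame_index = 1L) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  magic <- toks[1]
  if (!magic %in% c("P2", "P3")) stopf("unsupported NetPBM magic '%s'", magic)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxval <- as.integer(toks[4])
  vals <- as.numeric(toks[-(1:4)]) * (255 / maxval)
  if (magic == "P2") {
    if (length(vals) != w * h) stopf("PGM pixel count mismatch")
    tf_frame(matrix(vals, nrow = h, ncol = w, byrow = TRUE),
             timestamp, "thermal", frame_index)
  } else {
    if (length(vals) != 3L * w * h) stopf("PPM pixel count mismatch")
    px <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      px[, , ch] <- matrix(vals[seq(ch, by = 3L, length.out = w * h)],
                           nrow = h, ncol = w, byrow = TRUE)
    }
    tf_frame(px, timestamp, "visual", frame_index)
  }
}

#' Read a frame sequence with a timestamp sidecar
#'
#' The sidecar CSV has columns `frame_index`, `timestamp`, `file` (paths
#' relative to the CSV's directory).
#'
#' @param sidecar_csv Path to the sidecar CSV.
#' @return A list of [tf_frame].
#' @export
read_frame_sequence <- function(sidecar_csv) {
  tab <- utils::read.csv(sidecar_csv, stringsAsFactors = FALSE)
  need <- c("frame_index", "timestamp", "file")
  if (!all(need %in% names(tab)))
    stopf("sidecar must have columns %s", paste(need, collapse = ", "))
  base <- dirname(sidecar_csv)
  lapply(seq_len(nrow(tab)), function(i) {
    read_frame(file.path(base, tab$file[i]),
               timestamp = tab$timestamp[i],
               frame_index = tab$frame_index[i])
  })
}
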