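# Independent brute-force oracles used to freeze expected values.  These
# deliberately re-derive each quantity with naive loops, staying independent
# of the implementation paths they check.

# naive k x k neighbourhood median with edge replication
oracle_median_filter <- function(px, kernel) {
  h <- nrow(px); w <- ncol(px); r <- (kernel - 1) %/% 2
  out <- px
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      vals <- c()
      for (di in -r:r) for (dj in -r:r) {
        ii <- min(max(i + di, 1), h); jj <- min(max(j + dj, 1), w)
        vals <- c(vals, px[ii, jj])
      }
      out[i, j] <- median(vals)
    }
  }
  out
}

# nearest-neighbour tick matching oracle for stream pairing
oracle_pair_count <- function(vt, tt, rate_hz) {
  period <- 1 / rate_hz
  t0 <- max(vt[1], tt[1]); t1 <- min(vt[length(vt)], tt[length(tt)])
  if (t1 < t0) return(list(n = 0L, ticks = numeric(0)))
  ticks <- seq(t0, t1, by = period)
  keep <- vapply(ticks, function(tk) {
    min(abs(vt - tk)) <= period / 2 && min(abs(tt - tk)) <= period / 2
  }, logical(1))
  list(n = sum(keep), ticks = ticks[keep])
}

# literal Table-style statistics via scalar loops
oracle_static_features <- function(px) {
  m <- nrow(px); n <- ncol(px)
  mu <- sum(px) / (m * n)
  v <- if (m * n > 1) sum((px - mu)^2) / (m * n - 1) else 0
  med <- median(as.vector(px))
  rv <- rm <- numeric(m)
  for (i in seq_len(m)) {
    row <- px[i, ]
    rv[i] <- if (n > 1) sum((row - mean(row))^2) / (n - 1) else 0
    rm[i] <- median(row)
  }
  cv <- cm <- numeric(n)
  for (j in seq_len(n)) {
    col <- px[, j]
    cv[j] <- if (m > 1) sum((col - mean(col))^2) / (m - 1) else 0
    cm[j] <- median(col)
  }
  c(mu, v, med, mean(rv), mean(rm), mean(cv), mean(cm))
}

# exact two-sided signed-rank p-value by enumerating all 2^n sign
# assignments of the midranks (zeros already removed)
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    sum(r[signs])
  }, numeric(1))
  min(1, 2 * min(mean(ws <= W + 1e-9), mean(ws >= W - 1e-9)))
}

# softmax of negative absolute normalized deviations, straight from the
# defining formula
oracle_location_probs <- function(corners_b, corners_a, Wb, Hb, WA, HA) {
  ex <- exp(-abs(corners_b[, 1] / Wb - corners_a[, 1] / WA))
  ey <- exp(-abs(corners_b[, 2] / Hb - corners_a[, 2] / HA))
  list(pbx = ex / sum(ex), pby = ey / sum(ey),
       pb = pmin(ex / sum(ex), ey / sum(ey)))
}

# build a valid ROI set from an 11 x 2 corner matrix
make_roi_set <- function(corners, head = c(0, 0, 100, 120), frame_index = 1L,
                         side = 5, annotated = FALSE) {
  facial <- lapply(1:11, function(k)
    tf_roi_box(corners[k, 1], corners[k, 2], side, side, roi_id = k))
  tf_roi_set(tf_roi_box(head[1], head[2], head[3], head[4], 0L),
             facial, frame_index = frame_index, annotated = annotated)
}

# canonical annotated layout used across relocation tests
test_annotation <- function() {
  corners <- cbind(seq(10, 80, length.out = 11), seq(12, 96, length.out = 11))
  make_roi_set(corners, head = c(0, 0, 100, 120), annotated = TRUE)
}

expect_rois_equal <- function(a, b, tol = 1e-9) {
  expect_equal(roi_corners(a), roi_corners(b), tolerance = tol,
               ignore_attr = TRUE)
}
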