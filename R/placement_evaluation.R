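# Placement accuracy evaluation.
#
# Automatic ROI corners are compared to expert-annotated corners by the
# Euclidean distance D = sqrt((Ax-Mx)^2 + (Ay-My)^2); D close to zero means
# high accuracy.  Distances are summarized per ROI (mean +/- standard
# error) and the raw-vs-relocated comparison is tested per ROI with the
# Wilcoxon signed-rank test for zero median.

#' Euclidean distance between an automatic and a manual corner
#'
#' @param auto,manual Length-2 numeric `(x, y)` corners.
#' @return The distance D >= 0 (0 iff the corners coincide).
#' @export
corner_distance <- function(auto, manual) {
  if (length(auto) != 2L || length(manual) != 2L ||
      any(!is.finite(c(auto, manual))))
    stopf("corners must be finite (x, y) pairs")
  sqrt(sum((as.numeric(auto) - as.numeric(manual))^2))
}

#' Compare ROI placements against a manual reference
#'
#' One row per ROI: the automatic and manual left-upper corners and their
#' distance, tagged with the placement method.
#'
#' @param auto [tf_roi_set] produced automatically.
#' @param manual Expert [tf_roi_set] for the same frame.
#' @param method Tag, e.g. `"raw"` or `"relocated"`.
#' @return Data frame `frame_index, roi_id, method, ax, ay, mx, my, d`.
#' @export
compare_placements <- function(auto, manual, method = "raw") {
  stopifnot(inherits(auto, "tf_roi_set"), inherits(manual, "tf_roi_set"))
  ca <- roi_corners(auto); cm <- roi_corners(manual)
  data.frame(frame_index = auto$frame_index, roi_id = 1:11, method = method,
             ax = ca[, 1], ay = ca[, 2], mx = cm[, 1], my = cm[, 2],
             d = sqrt(rowSums((ca - cm)^2)))
}

#' Per-ROI mean and standard error of placement distances
#'
#' @param comparisons Data frame from [compare_placements()] (possibly many
#'   frames / methods row-bound).
#' @return Data frame `roi_id, method, n, mean, se`; SE is `sd/sqrt(n)`,
#'   0 by convention for a single observation.
#' @export
summarize_by_roi <- function(comparisons) {
  if (nrow(comparisons) == 0L) stopf("no comparisons to summarize")
  out <- list()
  for (m in unique(comparisons$method)) {
    for (k in sort(unique(comparisons$roi_id))) {
      d <- comparisons$d[comparisons$method == m & comparisons$roi_id == k]
      if (length(d) == 0L) next
      se <- if (length(d) < 2L) 0 else stats::sd(d) / sqrt(length(d))
      out[[length(out) + 1L]] <- data.frame(roi_id = k, method = m,
                                            n = length(d), mean = mean(d),
                                            se = se)
    }
  }
  do.call(rbind, out)
}

# Exact null distribution of the signed-rank statistic W+ with midrank ties,
# by generating-function convolution over doubled ranks (so half-integer
# midranks become integers).  Equivalent to enumerating all 2^n sign
# assignments.
signed_rank_exact_dist <- function(ranks2) {
  total <- sum(ranks2)
  probs <- numeric(total + 1L)  # index s+1 holds P(2*W+ = s)
  probs[1] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), probs[seq_len(total + 1L - r)])
    probs <- 0.5 * (probs + shifted)
  }
  probs
}

#' Wilcoxon signed-rank test for zero median
#'
#' Zeros are discarded, absolute differences are ranked with midranks for
#' ties, and W+ (sum of ranks of positive differences) is tested two-sided.
#' For n <= 25 the exact null distribution is used (computed by convolution
#' over sign assignments, so midrank ties are handled exactly); for larger n
#' a normal approximation with continuity correction and tie-corrected
#' variance is used.  Significance stars: n.s. (p > 0.05), * (<= 0.05),
#' ** (<= 0.01), *** (<= 0.001), >*** (<= 0.0001).
#'
#' @param differences Numeric vector of paired differences.
#' @param exact_max Largest n for which the exact branch is used (25).
#' @return A list: `statistic` (W+), `n` (nonzero differences), `p_value`,
#'   `stars`, `method` ("exact" / "normal" / "degenerate").  All-zero input
#'   yields the flagged degenerate result (p = 1, method "degenerate").
#' @export
wilcoxon_zero_median <- function(differences, exact_max = 25L) {
  d <- as.numeric(differences)
  if (length(d) == 0L || any(!is.finite(d))) stopf("differences must be finite and non-empty")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, n = 0L, p_value = 1, stars = "n.s.",
                method = "degenerate"))
  r <- rank(abs(d))  # midranks for ties
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    ranks2 <- as.integer(round(2 * r))
    probs <- signed_rank_exact_dist(ranks2)
    w2 <- as.integer(round(2 * W))
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):length(probs)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = W, n = n, p_value = p, stars = p_stars(p), method = method)
}

#' Significance stars for a p-value
#' @param p A p-value.
#' @return `"n.s."`, `"*"`, `"**"`, `"***"` or `">***"`.
#' @export
p_stars <- function(p) {
  if (p > 0.05) "n.s."
  else if (p > 0.01) "*"
  else if (p > 0.001) "**"
  else if (p > 0.0001) "***"
  else ">***"
}

#' Full placement evaluation report
#'
#' Per-ROI mean and SE for each method plus, when both a `"raw"` and a
#' `"relocated"` method are present, the per-ROI Wilcoxon signed-rank test
#' on the paired raw-minus-relocated distances.
#'
#' @param comparisons Row-bound [compare_placements()] output for both
#'   methods across frames.
#' @return Data frame `roi_id, method, n, mean, se, p, stars` (p/stars on
#'   the raw rows, NA elsewhere).
#' @export
placement_report <- function(comparisons) {
  summ <- summarize_by_roi(comparisons)
  summ$p <- NA_real_; summ$stars <- NA_character_
  methods <- unique(comparisons$method)
  if (all(c("raw", "relocated") %in% methods)) {
    for (k in sort(unique(comparisons$roi_id))) {
      raw <- comparisons[comparisons$method == "raw" & comparisons$roi_id == k, ]
      rel <- comparisons[comparisons$method == "relocated" & comparisons$roi_id == k, ]
      merged <- merge(raw, rel, by = "frame_index", suffixes = c(".raw", ".rel"))
      if (nrow(merged) == 0L) next
      wt <- wilcoxon_zero_median(merged$d.raw - merged$d.rel)
      i <- summ$roi_id == k & summ$method == "raw"
      summ$p[i] <- wt$p_value; summ$stars[i] <- wt$stars
    }
  }
  summ
}
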