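# Cross-camera registration.
#
# The visual and thermal cameras are rigidly mounted with nearly coincident
# fields of view; a single 3x3 homography estimated from chessboard point
# correspondences maps visual-plane pixels onto the thermal plane.  The face
# is not planar, so the homography is an approximation, but with the small
# camera baseline it is the standard and effective one.

#' Construct a homography
#'
#' @param matrix A 3x3 invertible matrix; it is renormalized so the
#'   lower-right element equals 1.
#' @return An object of class `tf_homography`.
#' @export
tf_homography <- function(matrix) {
  m <- as.matrix(matrix)
  if (!all(dim(m) == c(3L, 3L)) || any(!is.finite(m)))
    stopf("homography must be a finite 3x3 matrix")
  if (abs(m[3, 3]) < 1e-12) stopf("homography has (3,3) element ~ 0; cannot normalize")
  m <- m / m[3, 3]
  if (abs(det(m)) < 1e-12) stopf("homography is singular")
  structure(list(matrix = m), class = "tf_homography")
}

#' @export
print.tf_homography <- function(x, ...) {
  cat("<tf_homography>\n"); print(x$matrix); invisible(x)
}

#' Invert a homography
#' @param h A [tf_homography].
#' @return The inverse [tf_homography].
#' @export
invert_homography <- function(h) {
  stopifnot(inherits(h, "tf_homography"))
  tf_homography(solve(h$matrix))
}

# Hartley normalization: translate points to zero centroid and scale so the
# mean distance from the origin is sqrt(2).  Returns the 3x3 conditioning
# transform.
normalizing_transform <- function(pts) {
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  md <- mean(d)
  s <- if (md < 1e-12) 1 else sqrt(2) / md
  matrix(c(s, 0, -s * ctr[1],
           0, s, -s * ctr[2],
           0, 0, 1), nrow = 3, byrow = TRUE)
}

#' Estimate the visual-to-thermal homography by normalized DLT
#'
#' Direct Linear Transform with Hartley-style coordinate normalization
#' (zero centroid, mean distance sqrt(2)) for numerical conditioning.  The
#' algebraic least-squares solution is the smallest-singular-value right
#' singular vector of the 2n x 9 design matrix; when the correspondences are
#' generated by a true homography the estimate is exact to numerical
#' tolerance.
#'
#' @param correspondences A data frame (or matrix) with columns
#'   `vx, vy, tx, ty`: visual-plane points and their thermal-plane images.
#' @return A [tf_homography] mapping visual to thermal coordinates.
#' @export
estimate_homography <- function(correspondences) {
  m <- as.matrix(as.data.frame(correspondences)[, c("vx", "vy", "tx", "ty")])
  if (any(!is.finite(m))) stopf("correspondences must be finite")
  n <- nrow(m)
  if (n < 4L) stopf("at least 4 correspondences are required (got %d)", n)
  src <- m[, 1:2, drop = FALSE]; dst <- m[, 3:4, drop = FALSE]
  # degenerate if all source (or destination) points are collinear
  collinear <- function(p) {
    pc <- sweep(p, 2, colMeans(p))
    svd(pc)$d[2] < 1e-8 * max(1, svd(pc)$d[1])
  }
  if (collinear(src) || collinear(dst))
    stopf("degenerate configuration: points are collinear")
  Ts <- normalizing_transform(src)
  Td <- normalizing_transform(dst)
  hs <- cbind(src, 1) %*% t(Ts)
  hd <- cbind(dst, 1) %*% t(Td)
  A <- matrix(0, nrow = 2 * n, ncol = 9)
  for (i in seq_len(n)) {
    x <- hs[i, 1]; y <- hs[i, 2]
    u <- hd[i, 1]; v <- hd[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ]     <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  sv <- svd(A, nu = 0, nv = 9)
  hvec <- sv$v[, 9]
  Hn <- matrix(hvec, nrow = 3, byrow = TRUE)
  H <- solve(Td) %*% Hn %*% Ts
  if (abs(H[3, 3]) < 1e-12 || abs(det(H)) < 1e-12)
    stopf("degenerate configuration: estimated homography is singular")
  tf_homography(H)
}

#' Apply a homography to a point
#'
#' Standard projective transform with de-homogenization.
#'
#' @param h A [tf_homography].
#' @param point Numeric length-2 vector `(x, y)`.
#' @return The mapped `(x, y)`.
#' @export
apply_homography <- function(h, point) {
  stopifnot(inherits(h, "tf_homography"))
  if (length(point) != 2L || any(!is.finite(point))) stopf("point must be finite (x, y)")
  p <- h$matrix %*% c(point[1], point[2], 1)
  if (abs(p[3]) < 1e-12) stopf("point maps to infinity (w ~ 0)")
  c(p[1], p[2]) / p[3]
}

#' Project an ROI box through a homography
#'
#' The four corners of the half-open box are mapped and the axis-aligned
#' bounding box of their images is returned, rounded to integer pixels
#' (half away from zero) with width/height at least 1.  Keeps the
#' axis-aligned ROI contract downstream even under perspective maps.
#'
#' @param h A [tf_homography].
#' @param box A [tf_roi_box].
#' @return A [tf_roi_box] on the destination plane (same `roi_id`).
#' @export
project_box <- function(h, box) {
  stopifnot(inherits(h, "tf_homography"), inherits(box, "tf_roi_box"))
  corners <- rbind(c(box$x, box$y),
                   c(box$x + box$w, box$y),
                   c(box$x, box$y + box$h),
                   c(box$x + box$w, box$y + box$h))
  mapped <- t(apply(corners, 1, function(p) apply_homography(h, p)))
  x0 <- round_half_away(min(mapped[, 1])); x1 <- round_half_away(max(mapped[, 1]))
  y0 <- round_half_away(min(mapped[, 2])); y1 <- round_half_away(max(mapped[, 2]))
  tf_roi_box(x0, y0, max(1, x1 - x0), max(1, y1 - y0), roi_id = box$roi_id)
}

#' Write / read a homography as JSON (9 numbers, row-major)
#' @param h A [tf_homography].
#' @param path File path.
#' @export
write_homography <- function(h, path) {
  stopifnot(inherits(h, "tf_homography"))
  jsonlite::write_json(as.vector(t(h$matrix)), path, digits = NA)
  invisible(path)
}

#' @rdname write_homography
#' @export
read_homography <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(v) != 9L) stopf("homography JSON must hold 9 numbers")
  tf_homography(matrix(as.numeric(v), nrow = 3, byrow = TRUE))
}

#' Read chessboard correspondences from CSV
#'
#' Columns `vx, vy, tx, ty`.
#' @param path CSV path.
#' @return A data frame of correspondences.
#' @export
read_correspondences <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("vx", "vy", "tx", "ty")
  if (!all(need %in% names(tab)))
    stopf("correspondence CSV must have columns %s", paste(need, collapse = ", "))
  tab[, need]
}
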