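# Planar polygon helpers shared by outline processing, measurements and the
# synthetic generator. Outlines are n x 2 matrices (columns x, y), closed
# implicitly: the last vertex is not a repeat of the first.

#' Signed polygon area (shoelace)
#'
#' Positive for counter-clockwise traversal in a y-up coordinate system.
#'
#' @param xy numeric matrix with columns x, y; closed polygon, first vertex
#'   not repeated.
#' @return signed area (numeric scalar).
#' @keywords internal
polygon_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon perimeter
#' @inheritParams polygon_signed_area
#' @keywords internal
polygon_perimeter <- function(xy) {
  d <- xy[c(seq_len(nrow(xy))[-1], 1), , drop = FALSE] - xy
  sum(sqrt(rowSums(d^2)))
}

#' Maximum Feret diameter of a point set
#'
#' Exact maximum pairwise distance, computed on the convex hull (rotating
#' through all hull vertex pairs; hulls of traced outlines are small).
#'
#' @param xy numeric matrix with columns x, y.
#' @return list with `length` (the diameter), `angle` (direction in radians,
#'   in `[0, pi)`), and the index pair `ij`.
#' @keywords internal
feret_diameter <- function(xy) {
  h <- grDevices::chull(xy)
  p <- xy[h, , drop = FALSE]
  n <- nrow(p)
  if (n == 1L) return(list(length = 0, angle = 0, ij = c(h[1], h[1])))
  dx <- outer(p[, 1], p[, 1], "-")
  dy <- outer(p[, 2], p[, 2], "-")
  d2 <- dx^2 + dy^2
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  ang <- atan2(p[ij[2], 2] - p[ij[1], 2], p[ij[2], 1] - p[ij[1], 1]) %% pi
  list(length = sqrt(max(d2)), angle = ang, ij = h[ij])
}

# Extent of the point cloud along direction `angle` (max projection spread).
directional_extent <- function(xy, angle) {
  pr <- xy[, 1] * cos(angle) + xy[, 2] * sin(angle)
  max(pr) - min(pr)
}

# Rotate points by `theta` radians about the origin (counter-clockwise, y up).
rotate_points <- function(xy, theta) {
  ct <- cos(theta); st <- sin(theta)
  cbind(x = xy[, 1] * ct - xy[, 2] * st,
        y = xy[, 1] * st + xy[, 2] * ct)
}
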