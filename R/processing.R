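# Outline conditioning: smoothing, rotation/size normalization, and polar
# (radial-profile) sampling. Everything downstream of the tracer works in
# mathematical orientation (y up, angles counter-clockwise from +x).

#' Smooth a closed outline by a weighted moving average
#'
#' Each iteration replaces every vertex p_i by (p_{i-1} + 2 p_i + p_{i+1}) / 4
#' with cyclic indexing. The (1,2,1)/4 kernel preserves straight edges and
#' contracts curvature toward the centroid, damping single-pixel noise while
#' leaving low-frequency shape almost untouched.
#'
#' @param outline numeric matrix with columns x, y (closed polygon, first
#'   vertex not repeated).
#' @param iterations number of smoothing passes (>= 1).
#' @return smoothed outline matrix of identical dimensions.
#' @examples
#' sq <- cbind(x = c(1, -1, -1, 1), y = c(1, 1, -1, -1))
#' smooth_outline(sq, 1)  # corners pulled halfway toward edge midpoints
#' @export
smooth_outline <- function(outline, iterations = 1L) {
  outline <- as_outline_matrix(outline)
  if (nrow(outline) < 3L) stop("outline must have at least 3 points")
  if (iterations < 1L) stop("iterations must be >= 1")
  n <- nrow(outline)
  im <- c(n, seq_len(n - 1L))
  ip <- c(seq_len(n)[-1L], 1L)
  for (k in seq_len(iterations)) {
    outline <- (outline[im, , drop = FALSE] + 2 * outline +
                  outline[ip, , drop = FALSE]) / 4
  }
  outline
}

#' Normalize an outline for position, rotation and size
#'
#' Centers the outline on its centroid (the mean of the x and y vertex
#' coordinates), rotates it so the longest axis (maximum Feret diameter
#' direction) is horizontal, and scales it uniformly so the enclosed polygon
#' area equals 1. Input in raster coordinates (y down) is flipped into
#' mathematical orientation (y up) first when `raster = TRUE`. The 180-degree
#' ambiguity left by axis alignment is resolved by putting the longer
#' horizontal extent from the centroid on the positive-x side, so equally
#' oriented images normalize consistently.
#'
#' @param outline numeric matrix with columns x, y.
#' @param raster logical; is the input in raster convention (y down)? Traced
#'   outlines are; analytic test shapes usually are not.
#' @return an outline matrix (class `oto_normalized`) with vertex-mean
#'   centroid at the origin, longest axis horizontal, polygon area 1, and
#'   counter-clockwise traversal.
#' @export
normalize_outline <- function(outline, raster = FALSE) {
  xy <- as_outline_matrix(outline)
  if (raster) xy[, 2] <- -xy[, 2]
  if (abs(polygon_signed_area(xy)) < .Machine$double.eps * nrow(xy))
    stop("degenerate outline: zero enclosed area")
  # consistent counter-clockwise traversal
  if (polygon_signed_area(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  xy <- sweep(xy, 2, colMeans(xy))
  fer <- feret_diameter(xy)
  xy <- rotate_points(xy, -fer$angle)
  xy <- sweep(xy, 2, colMeans(xy))  # rotation is exact; re-center for safety
  if (max(xy[, 1]) < -min(xy[, 1])) {
    xy <- -xy  # rotate by pi: longer horizontal reach points right
  }
  a <- abs(polygon_signed_area(xy))
  xy <- xy / sqrt(a)
  xy <- sweep(xy, 2, colMeans(xy))
  colnames(xy) <- c("x", "y")
  class(xy) <- c("oto_normalized", class(xy))
  xy
}

#' Sample a radial profile at equidistant angles
#'
#' Draws `n_angles` rays from the vertex-mean centroid, starting at the
#' 0-degree radial (horizontally to the right) and proceeding
#' counter-clockwise, and records the distance from the centroid to the
#' outline along each ray. Crossings are found by exact ray/segment
#' intersection (linear interpolation along the crossed segment). If a ray
#' crosses the outline more than once (outline not star-shaped about its
#' centroid) the farthest crossing is used and a warning is raised, preserving
#' the outer silhouette.
#'
#' @param outline outline matrix, typically from [normalize_outline()]; the
#'   centroid of its vertices must lie strictly inside the polygon.
#' @param n_angles number of rays; must be a power of two for the wavelet
#'   pathway (default 1024 = 2^10).
#' @return numeric vector of length `n_angles` (class `oto_radial`), entry k
#'   holding the radius at angle 360 * (k - 1) / n_angles degrees.
#' @export
radial_profile <- function(outline, n_angles = 1024L) {
  xy <- as_outline_matrix(outline)
  n_angles <- as.integer(n_angles)
  if (n_angles < 4L) stop("n_angles must be >= 4")
  ctr <- colMeans(xy)
  p <- sweep(xy, 2, ctr)
  n <- nrow(p)
  a <- p
  b <- p[c(seq_len(n)[-1L], 1L), , drop = FALSE]
  d <- b - a
  theta <- 2 * pi * (seq_len(n_angles) - 1L) / n_angles
  ux <- cos(theta); uy <- sin(theta)
  # solve a + s d = t u per (ray, segment); det = u x d (cross product)
  radii <- numeric(n_angles)
  multi <- FALSE
  chunk <- 128L
  num_t_seg <- a[, 2] * d[, 1] - a[, 1] * d[, 2]  # a x d, per segment
  for (i0 in seq(1L, n_angles, by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, n_angles)
    det <- outer(uy[ii], d[, 1]) - outer(ux[ii], d[, 2])       # u x d
    s <- (outer(ux[ii], a[, 2]) - outer(uy[ii], a[, 1])) / det # u x a / det
    tt <- matrix(num_t_seg, nrow = length(ii), ncol = n, byrow = TRUE) / det
    # half-open window with a float tolerance so a crossing at a shared
    # vertex is claimed by exactly one of the two adjacent segments
    hit <- is.finite(s) & s >= -1e-9 & s < 1 - 1e-9 & tt > 0
    tt[!hit] <- NA_real_
    nhit <- rowSums(hit)
    if (any(nhit == 0L))
      stop("ray with no outline crossing: centroid outside the polygon?")
    if (any(nhit > 1L)) multi <- TRUE
    radii[ii] <- apply(tt, 1L, max, na.rm = TRUE)
  }
  if (multi)
    warning("outline is not star-shaped about its centroid; ",
            "using the farthest crossing per ray")
  structure(radii, class = "oto_radial", centroid = ctr)
}

#' Convert a radial profile back to a closed outline
#'
#' @param radii numeric vector of radii at equidistant counter-clockwise
#'   angles starting at 0 degrees.
#' @param centroid optional centre (default origin).
#' @return outline matrix with one vertex per radius.
#' @export
profile_to_outline <- function(radii, centroid = c(0, 0)) {
  n <- length(radii)
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(x = centroid[1] + radii * cos(theta),
        y = centroid[2] + radii * sin(theta))
}

# Accept matrices, data frames or the package's classed outlines.
as_outline_matrix <- function(outline) {
  if (is.data.frame(outline)) outline <- as.matrix(outline[, c("x", "y")])
  if (!is.matrix(outline) || ncol(outline) < 2L)
    stop("outline must be a two-column (x, y) matrix")
  m <- unclass(outline)[, 1:2, drop = FALSE]
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y")
  m
}
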