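# Raster handling: JPEG I/O through EBImage, grayscale conversion,
# thresholding and Moore-neighbour contour tracing. Images are numeric
# matrices in [0, 1], indexed [row, col] = [y, x], origin top-left.

#' Read an image as a grayscale intensity matrix
#'
#' Color images are reduced to luminance (0.2126 R + 0.7152 G + 0.0722 B).
#'
#' @param path image file (JPEG or PNG).
#' @return numeric matrix in `[0, 1]`, rows = y (top-down), cols = x.
#' @export
read_gray <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  a <- EBImage::imageData(img)
  if (length(d) == 3L && d[3] >= 3L) {
    g <- 0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3]
  } else if (length(d) == 3L) {
    g <- a[, , 1]
  } else {
    g <- a
  }
  # EBImage stores [x, y]; transpose to [row = y, col = x]
  t(g)
}

# read full color as [y, x, channel] array in [0,1]
read_color <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  aperm(a[, , 1:3, drop = FALSE], c(2L, 1L, 3L))
}

write_jpeg_raster <- function(arr, path, quality = 95L) {
  # arr: [y, x] matrix or [y, x, 3] array in [0,1]
  arr <- pmin(pmax(arr, 0), 1)
  a <- if (length(dim(arr)) == 3L) aperm(arr, c(2L, 1L, 3L)) else t(arr)
  img <- EBImage::Image(a, colormode = if (length(dim(arr)) == 3L) "Color" else "Grayscale")
  EBImage::writeImage(img, path, quality = quality)
  invisible(path)
}

#' Binarize a grayscale image by an intensity threshold
#'
#' A pixel is foreground iff its intensity is strictly greater than
#' `threshold`; this separates a bright otolith from the dark background.
#'
#' @param image numeric matrix in `[0, 1]` (rows = y, cols = x), or a color
#'   array `[y, x, 3]` which is converted to luminance first.
#' @param threshold intensity threshold in (0, 1); default 0.2.
#' @return logical matrix, TRUE = foreground.
#' @export
binarize <- function(image, threshold = 0.2) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (length(dim(image)) == 3L)
    image <- 0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3]
  fg <- image > threshold
  if (!any(fg))
    stop("empty foreground at threshold ", threshold,
         "; try a lower threshold")
  if (any(fg[1, ]) || any(fg[nrow(fg), ]) || any(fg[, 1]) || any(fg[, ncol(fg)]))
    warning("foreground touches the image border; contour may be clipped")
  fg
}

#' Trace the closed boundary of a foreground component
#'
#' Selects a connected component of the binary image (8-connectivity) and
#' traces its outer boundary with Moore-neighbour tracing using Jacob's
#' stopping criterion, returning an ordered closed contour of boundary
#' pixels. With an explicit `seed` the component containing (or nearest to,
#' within `search_radius`) the seed is traced; otherwise the component at
#' the image centre, falling back to the largest component.
#'
#' @param binary logical matrix (TRUE = foreground), rows = y, cols = x.
#' @param seed optional c(x, y) pixel coordinate near the target component.
#' @param search_radius pixels to search around an explicit seed before
#'   giving up (default: a quarter of the smaller image dimension).
#' @param min_boundary minimum boundary length accepted (smaller components
#'   are rejected as noise specks).
#' @return integer matrix with columns x, y (class `oto_outline`): ordered
#'   boundary pixels, consecutive points 8-adjacent, last adjacent to first,
#'   first point not repeated at the end.
#' @export
trace_contour <- function(binary, seed = NULL,
                          search_radius = NULL, min_boundary = 10L) {
  stopifnot(is.matrix(binary))
  mode(binary) <- "logical"
  lab <- EBImage::bwlabel(EBImage::Image(t(binary)))
  lab <- t(EBImage::imageData(lab))  # [y, x] integer labels, 0 = background
  h <- nrow(binary); w <- ncol(binary)
  explicit <- !is.null(seed)
  if (is.null(seed)) seed <- c(round(w / 2), round(h / 2))
  sx <- as.integer(round(seed[1])); sy <- as.integer(round(seed[2]))
  sx <- min(max(sx, 1L), w); sy <- min(max(sy, 1L), h)
  target <- lab[sy, sx]
  if (target == 0L) {
    if (explicit) {
      if (is.null(search_radius)) search_radius <- floor(min(h, w) / 4)
      idx <- which(lab > 0L, arr.ind = TRUE)
      d2 <- (idx[, 2] - sx)^2 + (idx[, 1] - sy)^2
      if (!length(d2) || min(d2) > search_radius^2)
        stop("no foreground component within ", search_radius,
             " px of seed (", sx, ", ", sy, ")")
      nearest <- idx[which.min(d2), ]
      target <- lab[nearest[1], nearest[2]]
    } else {
      tab <- tabulate(lab[lab > 0L])
      if (!length(tab)) stop("no foreground component in image")
      target <- which.max(tab)
    }
  }
  comp <- lab == target
  # boundary start: from the seed's row within the component, walk +x to the
  # last foreground pixel before background (the right edge of the blob)
  row0 <- if (comp[sy, sx]) sy else which(rowSums(comp) > 0L)[1L]
  xs <- which(comp[row0, ])
  x0 <- max(xs)
  start <- c(row0, x0)              # (y, x)
  # Moore neighbourhood, clockwise in raster coords, starting east
  nb <- rbind(c(0, 1), c(1, 1), c(1, 0), c(1, -1),
              c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1))  # (dy, dx)
  inside <- function(p) p[1] >= 1L && p[1] <= h && p[2] >= 1L && p[2] <= w
  fg <- function(p) inside(p) && comp[p[1], p[2]]
  # Moore tracing with a backtrack *position*: scan the 8-neighbourhood of the
  # current pixel clockwise starting from the backtrack cell; the first
  # foreground cell becomes current, the cell examined just before it becomes
  # the new backtrack. The walk is a deterministic orbit over (pixel,
  # backtrack-direction) states, so it terminates exactly when a state
  # repeats (Jacob's stopping criterion is the special case of re-entering
  # the start state); any pre-cycle tail is trimmed.
  start_back <- c(start[1], start[2] + 1L)  # east of the rightmost pixel: background
  cur <- start
  bpos <- start_back
  cap <- 4L * (h + w)
  pts_y <- integer(cap); pts_x <- integer(cap)
  np <- 0L
  seen <- new.env(hash = TRUE, parent = emptyenv())
  max_steps <- 8L * h * w
  step <- 0L
  i0 <- NA_integer_
  repeat {
    step <- step + 1L
    if (step > max_steps) stop("contour tracing failed to terminate")
    dvec <- bpos - cur
    d0 <- which(nb[, 1] == dvec[1] & nb[, 2] == dvec[2])
    state <- paste0(cur[1], ",", cur[2], ",", d0)
    prev_idx <- seen[[state]]
    if (!is.null(prev_idx)) { i0 <- prev_idx; break }
    np <- np + 1L
    if (np > cap) {
      cap <- 2L * cap
      length(pts_y) <- cap; length(pts_x) <- cap
    }
    pts_y[np] <- cur[1]; pts_x[np] <- cur[2]
    seen[[state]] <- np
    found <- FALSE
    prev <- bpos
    for (k in seq_len(8L)) {
      dir <- ((d0 - 1L + k) %% 8L) + 1L
      cand <- cur + nb[dir, ]
      if (fg(cand)) {
        cur <- cand
        bpos <- prev
        found <- TRUE
        break
      }
      prev <- cand
    }
    if (!found) { i0 <- 1L; break }  # isolated single pixel
  }
  idx <- i0:np
  out <- cbind(x = pts_x[idx], y = pts_y[idx])
  colnames(out) <- c("x", "y")
  if (nrow(out) < min_boundary)
    stop("component boundary has only ", nrow(out),
         " pixels (< ", min_boundary, "); likely a noise speck")
  structure(out, class = c("oto_outline", class(out)))
}
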