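# Elliptic Fourier decomposition of closed outlines (Kuhl-Giardina), with the
# standard size/rotation/starting-point normalization. The curve is
# parameterized by cumulative chord length, which makes the coefficients
# robust to the uneven vertex spacing produced by contour tracing.

#' Elliptic Fourier decomposition of a closed outline
#'
#' Decomposes the closed curve (x(t), y(t)), parameterized by cumulative
#' chord length, into `harmonics` harmonic ellipses. Harmonic h contributes
#' a_h cos(2 pi h t/T) + b_h sin(...) to x and c_h cos + d_h sin to y.
#'
#' @param outline numeric matrix with columns x, y (closed polygon, first
#'   vertex not repeated).
#' @param harmonics number of harmonics H; needs at least 2H + 1 vertices.
#' @return list of class `oto_efd`: `an`, `bn`, `cn`, `dn` (length H),
#'   `A0`, `C0` (curve centre terms), and `T` (total chord length).
#' @export
efourier <- function(outline, harmonics = 12L) {
  xy <- as_outline_matrix(outline)
  n <- nrow(xy)
  if (n < 2L * harmonics + 1L)
    stop("need at least ", 2L * harmonics + 1L, " outline points for ",
         harmonics, " harmonics (got ", n, ")")
  dxy <- xy[c(seq_len(n)[-1L], 1L), , drop = FALSE] - xy
  dt <- sqrt(rowSums(dxy^2))
  keep <- dt > 0
  if (!all(keep)) {
    xy <- xy[keep, , drop = FALSE]
    n <- nrow(xy)
    dxy <- dxy[keep, , drop = FALSE]
    dt <- dt[keep]
  }
  tt <- cumsum(dt)
  T_ <- tt[length(tt)]
  t0 <- c(0, tt[-length(tt)])
  an <- bn <- cn <- dn <- numeric(harmonics)
  vx <- dxy[, 1] / dt; vy <- dxy[, 2] / dt
  for (h in seq_len(harmonics)) {
    w <- 2 * pi * h / T_
    cos1 <- cos(w * t0); cos2 <- cos(w * tt)
    sin1 <- sin(w * t0); sin2 <- sin(w * tt)
    k <- T_ / (2 * pi^2 * h^2)
    an[h] <- k * sum(vx * (cos2 - cos1))
    bn[h] <- k * sum(vx * (sin2 - sin1))
    cn[h] <- k * sum(vy * (cos2 - cos1))
    dn[h] <- k * sum(vy * (sin2 - sin1))
  }
  # centre terms: mean of the piecewise-linear curve over arc length
  xn <- xy[c(seq_len(n)[-1L], 1L), , drop = FALSE]
  A0 <- sum(dt * (xy[, 1] + xn[, 1]) / 2) / T_
  C0 <- sum(dt * (xy[, 2] + xn[, 2]) / 2) / T_
  structure(list(an = an, bn = bn, cn = cn, dn = dn, A0 = A0, C0 = C0,
                 T = T_, harmonics = harmonics),
            class = "oto_efd")
}

#' Normalize elliptic Fourier coefficients
#'
#' Removes starting point, rotation, and size: the parameter origin is moved
#' to the first-harmonic ellipse's semi-major axis, the shape is rotated so
#' that axis is horizontal, and all coefficients are divided by the
#' semi-major axis length. After normalization a1 = 1, b1 = c1 = 0; those
#' three are dropped, leaving 4H - 3 values (45 for H = 12): d1 then
#' a2, b2, c2, d2, ..., aH..dH. Residual sign ambiguities (major-axis
#' direction, traversal orientation) are canonicalized by requiring a1 > 0
#' and d1 > 0, so any rotation, scaling, translation, starting point, or
#' traversal direction of the same shape yields the same vector.
#'
#' @param efd an `oto_efd` object from [efourier()].
#' @return named numeric vector `F1..F(4H-3)` of class `oto_efd_norm`, with
#'   attribute `d1` (= first element) and `scale` (semi-major axis length).
#' @export
normalize_efd <- function(efd) {
  stopifnot(inherits(efd, "oto_efd"))
  H <- efd$harmonics
  # canonical traversal orientation: a clockwise first-harmonic ellipse
  # (a1 d1 - b1 c1 < 0) is the time-reversed curve; reverse the parameter
  # (t -> -t flips the sine terms) before normalizing
  if (efd$an[1] * efd$dn[1] - efd$bn[1] * efd$cn[1] < 0) {
    efd$bn <- -efd$bn
    efd$dn <- -efd$dn
  }
  a1 <- efd$an[1]; b1 <- efd$bn[1]; c1 <- efd$cn[1]; d1 <- efd$dn[1]
  if (a1^2 + b1^2 + c1^2 + d1^2 < .Machine$double.eps)
    stop("degenerate first harmonic; cannot normalize")
  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1),
                       a1^2 + c1^2 - b1^2 - d1^2)
  norm_at <- function(theta) {
    an <- efd$an; bn <- efd$bn; cn <- efd$cn; dn <- efd$dn
    a2 <- an; b2 <- bn; c2 <- cn; d2 <- dn
    for (h in seq_len(H)) {
      ct <- cos(h * theta); st <- sin(h * theta)
      a2[h] <- an[h] * ct + bn[h] * st
      b2[h] <- -an[h] * st + bn[h] * ct
      c2[h] <- cn[h] * ct + dn[h] * st
      d2[h] <- -cn[h] * st + dn[h] * ct
    }
    psi <- atan2(c2[1], a2[1])
    cp <- cos(psi); sp <- sin(psi)
    a3 <- cp * a2 + sp * c2
    b3 <- cp * b2 + sp * d2
    c3 <- -sp * a2 + cp * c2
    d3 <- -sp * b2 + cp * d2
    list(an = a3, bn = b3, cn = c3, dn = d3, scale = a3[1])
  }
  # theta is defined modulo pi: both candidates put the start on the major
  # axis (at opposite ends) and the spatial rotation psi absorbs the sign,
  # leaving the even harmonics flipped between them. Canonicalize by the
  # sign of the first non-negligible even-harmonic coefficient.
  cand <- lapply(c(theta, theta + pi), function(th) {
    res <- norm_at(th)
    E <- res$scale
    list(an = res$an / E, bn = res$bn / E, cn = res$cn / E, dn = res$dn / E,
         scale = E)
  })
  pick_sign <- function(r) {
    ev <- seq(2, H, by = 2)
    v <- as.vector(rbind(r$an[ev], r$bn[ev], r$cn[ev], r$dn[ev]))
    nz <- which(abs(v) > 1e-7)
    if (!length(nz)) 1 else sign(v[nz[1]])
  }
  res <- if (pick_sign(cand[[1]]) >= 0) cand[[1]] else cand[[2]]
  an <- res$an; bn <- res$bn; cn <- res$cn; dn <- res$dn
  E <- res$scale
  vals <- c(dn[1])
  for (h in 2:H) vals <- c(vals, an[h], bn[h], cn[h], dn[h])
  names(vals) <- paste0("F", seq_along(vals))
  structure(vals, class = "oto_efd_norm", harmonics = H, scale = E)
}

#' Inverse elliptic Fourier synthesis
#'
#' Reconstructs a closed outline from elliptic Fourier coefficients, sampled
#' at `n_points` equidistant parameter values. Accepts a raw [efourier()]
#' object, a normalized vector from [normalize_efd()] (for which a1 = 1 and
#' b1 = c1 = 0 are reinstated), or such a plain numeric vector.
#'
#' @param efd coefficients (see above).
#' @param n_points number of points sampled along the curve.
#' @param harmonics optionally use only the first `harmonics` harmonics.
#' @return outline matrix with columns x, y.
#' @export
iefourier <- function(efd, n_points = 300L, harmonics = NULL) {
  if (inherits(efd, "oto_efd")) {
    an <- efd$an; bn <- efd$bn; cn <- efd$cn; dn <- efd$dn
    A0 <- efd$A0; C0 <- efd$C0
  } else {
    vals <- as.numeric(efd)
    if ((length(vals) + 3L) %% 4L != 0L)
      stop("normalized coefficient vector must have length 4H - 3")
    H <- (length(vals) + 3L) %/% 4L
    an <- c(1, vals[seq(2L, by = 4L, length.out = H - 1L)])
    bn <- c(0, vals[seq(3L, by = 4L, length.out = H - 1L)])
    cn <- c(0, vals[seq(4L, by = 4L, length.out = H - 1L)])
    dn <- c(vals[1L], vals[seq(5L, by = 4L, length.out = H - 1L)])
    A0 <- 0; C0 <- 0
  }
  H <- length(an)
  if (!is.null(harmonics)) {
    if (harmonics < 1L || harmonics > H) stop("harmonics must be in 1..", H)
    H <- as.integer(harmonics)
  }
  tt <- seq(0, 1, length.out = n_points + 1L)[-(n_points + 1L)]
  x <- rep(A0, n_points); y <- rep(C0, n_points)
  for (h in seq_len(H)) {
    ch <- cos(2 * pi * h * tt); sh <- sin(2 * pi * h * tt)
    x <- x + an[h] * ch + bn[h] * sh
    y <- y + cn[h] * ch + dn[h] * sh
  }
  cbind(x = x, y = y)
}
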