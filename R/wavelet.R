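# Periodized dyadic discrete wavelet transform of radial profiles.
#
# The radius-vs-angle signal is periodic by construction, so periodic
# boundary handling is exact (the transform matrix is orthogonal at every
# level and Parseval holds to machine precision). The filter is the
# Daubechies least-asymmetric (symlet) scaling filter with 8 vanishing
# moments, length 16; taps are the standard published values.

.sym8_lo <- c(
  -0.0033824159510061256, -0.0005421323317911481, 0.03169508781149298,
  0.007607487324917605, -0.1432942383508097, -0.061273359067658524,
  0.4813596512583722, 0.7771857517005235, 0.3644418948353314,
  -0.05194583810770904, -0.027219029917056003, 0.049137179673607506,
  0.003808752013890615, -0.01495225833704823, -0.0003029205147213668,
  0.0018899503327594609)

# Quadrature-mirror highpass: g[m] = (-1)^m h[L-1-m] (0-based).
.qmf <- function(h) rev(h) * (-1)^(seq_along(h) - 1L)

# One analysis step: x (length N, even) -> list(approx, detail), each N/2.
# a[k] = sum_m h[m] x[(2k + m) mod N], 0-based.
.dwt_step <- function(x, h, g) {
  n <- length(x)
  n2 <- n %/% 2L
  k2 <- 2L * (seq_len(n2) - 1L)
  a <- numeric(n2); d <- numeric(n2)
  for (m in seq_along(h)) {
    idx <- (k2 + (m - 1L)) %% n + 1L
    a <- a + h[m] * x[idx]
    d <- d + g[m] * x[idx]
  }
  list(approx = a, detail = d)
}

# One synthesis step (transpose of the analysis matrix):
# x[i] = sum_k a[k] h[(i - 2k) mod N] + d[k] g[(i - 2k) mod N].
.idwt_step <- function(a, d, h, g) {
  n2 <- length(a)
  n <- 2L * n2
  x <- numeric(n)
  k2 <- 2L * (seq_len(n2) - 1L)
  for (m in seq_along(h)) {
    idx <- (k2 + (m - 1L)) %% n + 1L
    contrib <- h[m] * a + g[m] * d
    x[idx] <- x[idx] + contrib
  }
  x
}

#' Full dyadic wavelet decomposition of a periodic signal
#'
#' Decomposes a length 2^J signal down to a single scaling coefficient,
#' using the Daubechies least-asymmetric filter with 8 vanishing moments and
#' periodic boundaries. Detail level j holds 2^j coefficients (j = 0 is the
#' coarsest); level J-1 is pixel-scale.
#'
#' @param x numeric vector, length a power of two (>= 2).
#' @return list with `scaling` (scalar) and `details` (list of numeric
#'   vectors, element j+1 = level-j details), plus `n` the input length.
#' @export
dwt_full <- function(x) {
  n <- length(x)
  if (n < 2L || bitwAnd(n, n - 1L) != 0L)
    stop("signal length must be a power of two (got ", n, ")")
  h <- .sym8_lo
  g <- .qmf(h)
  details <- vector("list", as.integer(log2(n)))
  a <- as.numeric(x)
  j <- length(details)
  while (length(a) > 1L) {
    st <- .dwt_step(a, h, g)
    details[[j]] <- st$detail
    a <- st$approx
    j <- j - 1L
  }
  structure(list(scaling = a, details = details, n = n), class = "oto_dwt")
}

#' Inverse dyadic wavelet transform
#'
#' Reconstructs the signal from a [dwt_full()] decomposition, optionally
#' using only the coarsest detail levels. `level` is the number of detail
#' levels included: 0 reconstructs from the scaling coefficient alone
#' (a constant at the mean radius), and `length(details)` (10 for a 1024
#' sample profile) gives exact reconstruction.
#'
#' @param dec an `oto_dwt` decomposition.
#' @param level integer in 0..J; number of coarsest detail levels retained.
#' @return numeric vector of length `dec$n`.
#' @export
dwt_reconstruct <- function(dec, level = length(dec$details)) {
  stopifnot(inherits(dec, "oto_dwt"))
  nj <- length(dec$details)
  if (level < 0 || level > nj) stop("level must be in 0..", nj)
  h <- .sym8_lo
  g <- .qmf(h)
  a <- dec$scaling
  for (j in seq_len(nj)) {
    d <- dec$details[[j]]
    if (j > level) d <- rep(0, length(d))
    a <- .idwt_step(a, d, h, g)
  }
  a
}

#' Wavelet shape coefficients of a radial profile
#'
#' Applies the full periodized wavelet transform to a 1024-sample radial
#' profile and retains the scaling coefficient plus detail levels 0..5:
#' 1 + (1 + 2 + 4 + 8 + 16 + 32) = 64 coefficients. Finer levels describe
#' pixel-scale noise and are discarded. Each detail coefficient is localized
#' in angle; the `angle` attribute gives the centre angle (degrees) of each
#' coefficient's support, with NA for the global scaling coefficient.
#'
#' @param profile numeric radial profile of length 1024 (2^10 equidistant
#'   angles), e.g. from [radial_profile()].
#' @param levels number of detail levels retained (default 6, giving 64
#'   coefficients from a 1024-sample profile).
#' @return numeric vector of length 64 (class `oto_wavelet`) named
#'   `W1..W64`, ordered scaling, then levels 0..5 coarse-to-fine; attributes
#'   `level` and `angle` describe each entry.
#' @export
wavelet_coefficients <- function(profile, levels = 6L) {
  x <- as.numeric(profile)
  n <- length(x)
  if (n != 1024L)
    stop("radial profile must have length 1024 (got ", n, ")")
  dec <- dwt_full(x)
  vals <- dec$scaling
  for (j in seq_len(levels)) vals <- c(vals, dec$details[[j]])
  am <- wavelet_angle_map(levels, n)
  names(vals) <- paste0("W", seq_along(vals))
  structure(vals, class = "oto_wavelet", level = am$level, angle = am$angle,
            n = n)
}

#' Reconstruct a radial profile from retained wavelet coefficients
#'
#' Rebuilds the 1024-sample radial profile from a 64-coefficient vector
#' (finer detail levels set to zero), or from a full [dwt_full()]
#' decomposition, using the coarsest `level` detail levels.
#'
#' @param coeffs an `oto_wavelet` 64-vector, a plain numeric vector laid out
#'   the same way, or an `oto_dwt` object.
#' @param level number of detail levels to use (0..10); defaults to all
#'   levels present.
#' @param n signal length for reconstruction when `coeffs` is a retained
#'   vector (default 1024).
#' @return numeric radial profile of length `n`.
#' @export
wavelet_reconstruct <- function(coeffs, level = NULL, n = 1024L) {
  if (inherits(coeffs, "oto_dwt")) {
    if (is.null(level)) level <- length(coeffs$details)
    return(dwt_reconstruct(coeffs, level))
  }
  vals <- as.numeric(coeffs)
  nj <- as.integer(log2(n))
  # how many full levels are present in the retained vector?
  present <- 0L
  used <- 1L
  while (present < nj && used + 2^present <= length(vals)) {
    used <- used + 2^present
    present <- present + 1L
  }
  if (used != length(vals))
    stop("coefficient vector length ", length(vals),
         " does not match scaling + complete detail levels")
  if (is.null(level)) level <- nj
  if (level < 0 || level > nj) stop("level must be in 0..", nj)
  details <- vector("list", nj)
  pos <- 2L
  for (j in seq_len(nj)) {
    len <- 2^(j - 1L)
    if (j <= present) {
      details[[j]] <- vals[pos:(pos + len - 1L)]
      pos <- pos + len
    } else {
      details[[j]] <- rep(0, len)
    }
  }
  dec <- structure(list(scaling = vals[1L], details = details, n = n),
                   class = "oto_dwt")
  dwt_reconstruct(dec, level)
}

.angle_map_cache <- new.env(parent = emptyenv())

# circular energy centroid (degrees) of the level-j basis function at k = 0;
# the sym8 cascade is not zero-phase, so this differs substantially from the
# naive bin centre and is what makes coefficient angles line up with the
# outline features they respond to
.level_offset <- function(j, n) {
  key <- paste0(n, ":", j)
  hit <- .angle_map_cache[[key]]
  if (!is.null(hit)) return(hit)
  dec <- dwt_full(rep(0, n))
  dec$details[[j]][1] <- 1
  x <- dwt_reconstruct(dec)
  w <- x^2 / sum(x^2)
  ang <- 2 * pi * (seq_len(n) - 1L) / n
  off <- (atan2(sum(w * sin(ang)), sum(w * cos(ang))) %% (2 * pi)) * 180 / pi
  .angle_map_cache[[key]] <- off
  off
}

#' Centre angles of retained wavelet coefficients
#'
#' The centre angle of each detail coefficient is the circular energy
#' centroid of its basis function (computed once per level by inverse
#' transform of a unit coefficient), so it accounts for the phase delay of
#' the wavelet filter cascade. Within a level, coefficients are equally
#' spaced at 360 / 2^level degrees.
#'
#' @param levels number of detail levels (default 6).
#' @param n underlying profile length (default 1024).
#' @return data.frame with columns `index`, `level`, `angle` (degrees; NA for
#'   the scaling coefficient).
#' @export
wavelet_angle_map <- function(levels = 6L, n = 1024L) {
  lev <- NA_integer_; ang <- NA_real_
  for (j in seq_len(levels)) {
    len <- 2^(j - 1L)
    off <- .level_offset(j, n)
    lev <- c(lev, rep(j - 1L, len))
    ang <- c(ang, (off + 360 * (seq_len(len) - 1L) / len) %% 360)
  }
  data.frame(index = seq_along(lev), level = lev, angle = ang)
}
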