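# Reconstruction quality: how closely truncated wavelet / Fourier
# representations reproduce each outline, as a function of the number of
# detail levels or harmonics retained.

# synthesize EFD at arbitrary normalized parameter values tt in [0,1)
.efd_synth_at <- function(efd, tt, harmonics) {
  x <- rep(efd$A0, length(tt)); y <- rep(efd$C0, length(tt))
  for (h in seq_len(harmonics)) {
    ch <- cos(2 * pi * h * tt); sh <- sin(2 * pi * h * tt)
    x <- x + efd$an[h] * ch + efd$bn[h] * sh
    y <- y + efd$cn[h] * ch + efd$dn[h] * sh
  }
  cbind(x = x, y = y)
}

#' Reconstruction-accuracy curves for wavelet and Fourier transforms
#'
#' For every outlined fish, measures how well the outline is reproduced as
#' detail levels (wavelet) or harmonics (Fourier) are added.
#' Wavelet accuracy is computed in the radial domain:
#' `100 * (1 - sum|r_hat - r| / sum r)` between the reconstructed and the
#' original 1024-sample radial profile. Fourier accuracy is computed in the
#' plane: `100 * (1 - mean point deviation / mean radius)` between the
#' synthesized curve (at the outline's own chord-length parameters) and the
#' outline vertices. Both are bounded above by 100; the wavelet curve
#' reaches exactly 100 at the full 10 levels (orthogonal transform).
#'
#' @param store an `otoshape_project` with outlines.
#' @param max_harmonics largest Fourier harmonic count evaluated
#'   (default 15).
#' @param n_angles radial-profile length (default 1024).
#' @return list of class `oto_recon` with elements `wavelet` and `fourier`,
#'   each a data.frame (`x`, `accuracy` = mean over fish) with the per-fish
#'   matrix in attribute `per_fish`.
#' @export
estimate_outline_reconstruction <- function(store, max_harmonics = 15L,
                                            n_angles = 1024L) {
  stopifnot(inherits(store, "otoshape_project"))
  keys <- names(store$outlines)
  if (!length(keys)) stop("no outlines present")
  nlev <- as.integer(log2(n_angles))
  wacc <- matrix(NA_real_, length(keys), nlev + 1L,
                 dimnames = list(keys, 0:nlev))
  facc <- matrix(NA_real_, length(keys), max_harmonics,
                 dimnames = list(keys, seq_len(max_harmonics)))
  for (i in seq_along(keys)) {
    norm <- normalize_outline(.analysis_outline(store, keys[i]), raster = TRUE)
    prof <- radial_profile(norm, n_angles)
    dec <- dwt_full(as.numeric(prof))
    for (lv in 0:nlev) {
      rec <- dwt_reconstruct(dec, lv)
      wacc[i, lv + 1L] <- 100 * (1 - sum(abs(rec - prof)) / sum(prof))
    }
    efd <- efourier(norm, max_harmonics)
    xy <- as_outline_matrix(norm)
    nv <- nrow(xy)
    dxy <- xy[c(seq_len(nv)[-1L], 1L), , drop = FALSE] - xy
    dt <- sqrt(rowSums(dxy^2))
    tt <- (cumsum(dt) - dt) / sum(dt)  # parameter of each vertex
    ctr <- colMeans(xy)
    mean_rad <- mean(sqrt(rowSums(sweep(xy, 2, ctr)^2)))
    for (h in seq_len(max_harmonics)) {
      rec <- .efd_synth_at(efd, tt, h)
      dev <- sqrt(rowSums((rec - xy)^2))
      facc[i, h] <- 100 * (1 - mean(dev) / mean_rad)
    }
  }
  structure(list(
    wavelet = structure(data.frame(x = 0:nlev, accuracy = colMeans(wacc)),
                        per_fish = wacc),
    fourier = structure(data.frame(x = seq_len(max_harmonics),
                                   accuracy = colMeans(facc)),
                        per_fish = facc)),
    class = "oto_recon")
}

#' Smallest level / harmonic count reaching a target accuracy
#'
#' @param curve one element of [estimate_outline_reconstruction()] (a
#'   data.frame with `x` and `accuracy`), or an `oto_recon` object together
#'   with `method`.
#' @param target_pct target mean accuracy in percent (e.g. 98.5).
#' @param method `"wavelet"` or `"fourier"` when `curve` is an `oto_recon`.
#' @return the smallest `x` whose mean accuracy is at least `target_pct`,
#'   or NA if the curve never reaches it.
#' @export
find_threshold_level <- function(curve, target_pct,
                                 method = c("wavelet", "fourier")) {
  if (inherits(curve, "oto_recon")) curve <- curve[[match.arg(method)]]
  ok <- which(curve$accuracy >= target_pct)
  if (!length(ok)) return(NA_integer_)
  curve$x[ok[1L]]
}

#' Plot the reconstruction-accuracy curves
#'
#' @param est an `oto_recon` object.
#' @param target_pct draw a vertical line at the first level/harmonic
#'   reaching this accuracy (default 98.5; NULL to omit).
#' @return `est`, invisibly.
#' @export
outline_reconstruction_plot <- function(est, target_pct = 98.5) {
  stopifnot(inherits(est, "oto_recon"))
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  for (m in c("wavelet", "fourier")) {
    cv <- est[[m]]
    graphics::plot(cv$x, cv$accuracy, type = "b", las = 1,
                   xlab = if (m == "wavelet") "Wavelet level" else "Harmonics",
                   ylab = "Reconstruction accuracy (%)",
                   main = if (m == "wavelet") "a) Wavelet" else "b) Fourier")
    if (!is.null(target_pct)) {
      xv <- find_threshold_level(cv, target_pct)
      if (!is.na(xv)) graphics::abline(v = xv, col = "red")
    }
  }
  invisible(est)
}
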