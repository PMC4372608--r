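# Synthetic fixtures: otolith-like blobs rendered on dark backgrounds with
# matching metadata, and Gaussian coefficient datasets with planted group /
# allometry structure. Blobs are star-shaped by construction,
# r(theta) = R * (1 + sum_k eps_k cos(k theta + phi_k)), which guarantees
# the radial-profile preconditions; the first-harmonic lobe is pointed at
# 180 degrees so the "rostrum to the left" image convention is honored.

#' Specify a synthetic otolith-like blob
#'
#' @param base_radius mean radius R in pixels.
#' @param amplitudes named numeric vector of harmonic amplitudes eps_k
#'   (names = harmonic order k).
#' @param phases phases phi_k in radians, same length as `amplitudes`.
#' @param fg,bg foreground / background intensity in `[0, 1]`.
#' @param noise_sd pixel-noise standard deviation; the fg - bg gap must
#'   exceed 3 * noise_sd.
#' @param width,height image size in pixels.
#' @return list of class `blob_spec`.
#' @export
blob_spec <- function(base_radius = 165,
                      amplitudes = c(`1` = 0.06, `2` = 0.12, `3` = 0.05,
                                     `4` = 0.03),
                      phases = c(pi, 0, 0.7, 2.1),
                      fg = 0.8, bg = 0.05, noise_sd = 0.02,
                      width = 800L, height = 600L) {
  stopifnot(length(amplitudes) == length(phases))
  if (fg - bg <= 3 * noise_sd)
    stop("foreground/background gap must exceed 3 * noise_sd")
  if (sum(abs(amplitudes)) >= 1)
    stop("harmonic amplitudes too large: radius would vanish")
  structure(list(base_radius = base_radius, amplitudes = amplitudes,
                 phases = phases, fg = fg, bg = bg, noise_sd = noise_sd,
                 width = as.integer(width), height = as.integer(height)),
            class = "blob_spec")
}

blob_radius_at <- function(spec, theta) {
  r <- rep(1, length(theta))
  k <- as.numeric(names(spec$amplitudes))
  for (i in seq_along(k))
    r <- r + spec$amplitudes[i] * cos(k[i] * theta + spec$phases[i])
  spec$base_radius * r
}

#' Render a blob specification to a grayscale raster
#'
#' Deterministic given `seed`. Errors if the blob would touch or exceed the
#' frame.
#'
#' @param spec a [blob_spec()].
#' @param seed integer seed for the pixel noise.
#' @return numeric intensity matrix in `[0, 1]`, rows = y, cols = x.
#' @export
render_blob <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "blob_spec"))
  w <- spec$width; h <- spec$height
  theta_chk <- seq(0, 2 * pi, length.out = 721L)
  rmax <- max(blob_radius_at(spec, theta_chk))
  if (min(blob_radius_at(spec, theta_chk)) <= 0)
    stop("blob radius vanishes; reduce amplitudes")
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  if (rmax >= min(cx, cy, w - cx, h - cy) - 1)
    stop("blob exceeds the image frame; reduce base_radius")
  xs <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  ys <- cy - matrix(seq_len(h), h, w)  # math orientation (y up)
  theta <- atan2(ys, xs)
  rr <- sqrt(xs^2 + ys^2)
  mask <- rr < blob_radius_at(spec, theta)
  img <- matrix(spec$bg, h, w)
  img[mask] <- spec$fg
  .with_seed(seed, {
    img <- img + matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w)
  })
  pmin(pmax(img, 0), 1)
}

#' Generate a complete synthetic project on disk
#'
#' Writes `Original/<AREA>/`, `Fixed/<AREA>/` JPEG trees and a `FISH.csv`
#' with columns `folder,picname,pop,length_cm,cal`, emulating the layout of
#' a real otolith image archive. Per-group shape differences (harmonic
#' amplitude offsets), an allometric relation between fish length and both
#' otolith size and elongation, and per-fish random shape variation are
#' planted as specified, so downstream group tests and length
#' standardization have known truth.
#'
#' @param dir project directory to create.
#' @param n_per_group named integer vector: fish per group (names = area /
#'   population codes). Default `c(IC = 65, NO = 65, SC = 30)`.
#' @param group_effects named list: per group, a named numeric vector of
#'   harmonic-amplitude offsets added to the base [blob_spec()] amplitudes.
#'   Default plants increasing third-harmonic offsets.
#' @param length_model list with `mean`, `sd` (fish length distribution,
#'   cm), `radius_per_cm` (otolith base radius px per cm of fish),
#'   `elong_per_cm` (second-harmonic amplitude change per cm: allometric
#'   shape effect).
#' @param shape_sd per-fish random amplitude jitter (sd).
#' @param cal pixels per mm written to the `cal` column.
#' @param seed integer seed; the whole project is deterministic given it.
#' @param width,height,quality image size and JPEG quality.
#' @return the project directory path, invisibly.
#' @export
make_project <- function(dir,
                         n_per_group = c(IC = 65L, NO = 65L, SC = 30L),
                         group_effects = list(IC = c(`3` = 0),
                                              NO = c(`3` = 0.025),
                                              SC = c(`3` = 0.05)),
                         length_model = list(mean = 30, sd = 2.5,
                                             radius_per_cm = 5.5,
                                             elong_per_cm = 0.004),
                         shape_sd = 0.008,
                         cal = 100,
                         seed = 1L,
                         width = 800L, height = 600L, quality = 95L) {
  stopifnot(!is.null(names(n_per_group)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("Original", "Fixed"))
    for (gname in names(n_per_group))
      dir.create(file.path(dir, sub, gname), recursive = TRUE,
                 showWarnings = FALSE)
  base <- blob_spec(width = width, height = height)
  rows <- list()
  .with_seed(seed, {
    station0 <- 403L
    for (gi in seq_along(n_per_group)) {
      gname <- names(n_per_group)[gi]
      ng <- n_per_group[[gi]]
      eff <- group_effects[[gname]]
      station <- station0 + gi - 1L
      for (f in seq_len(ng)) {
        len <- stats::rnorm(1, length_model$mean, length_model$sd)
        len <- max(len, length_model$mean - 3 * length_model$sd)
        amp <- base$amplitudes
        if (!is.null(eff))
          for (k in names(eff)) amp[k] <- (if (k %in% names(amp)) amp[k] else 0) + eff[[k]]
        amp["2"] <- amp["2"] +
          length_model$elong_per_cm * (len - length_model$mean)
        amp <- amp + stats::rnorm(length(amp), sd = shape_sd)
        ph <- base$phases + stats::rnorm(length(base$phases), sd = 0.05)
        ph[1] <- pi  # keep the rostrum lobe pointing left
        spec <- blob_spec(base_radius = length_model$radius_per_cm * len,
                          amplitudes = amp, phases = ph,
                          fg = base$fg, bg = base$bg,
                          noise_sd = base$noise_sd,
                          width = width, height = height)
        img_seed <- sample.int(.Machine$integer.max, 1L)
        img <- render_blob(spec, seed = img_seed)
        picname <- paste0(station, "_", f)
        path_fixed <- file.path(dir, "Fixed", gname, paste0(picname, ".jpg"))
        write_jpeg_raster(img, path_fixed, quality = quality)
        file.copy(path_fixed,
                  file.path(dir, "Original", gname, paste0(picname, ".jpg")),
                  overwrite = TRUE)
        rows[[length(rows) + 1L]] <-
          data.frame(folder = gname, picname = picname, pop = gname,
                     length_cm = round(len, 2), cal = cal,
                     stringsAsFactors = FALSE)
      }
    }
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "FISH.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Generate a synthetic coefficient dataset (no images)
#'
#' Gaussian fish x coefficient matrix with planted group mean offsets,
#' common length slopes, and group-specific interaction slopes, for testing
#' standardization and the downstream statistics directly.
#'
#' @param n_per_group named or unnamed integer vector of group sizes.
#' @param n_coef number of coefficients.
#' @param effect_matrix optional groups x coefficients matrix of group mean
#'   offsets (default all zero).
#' @param length_slopes numeric vector (recycled over coefficients): common
#'   slope of each coefficient on fish length.
#' @param interaction_slopes optional groups x coefficients matrix of
#'   additional group-specific slopes (default zero: no interaction).
#' @param length_mean,length_sd fish length distribution (cm).
#' @param noise_sd residual coefficient noise.
#' @param seed integer seed.
#' @return list with `coeffs` (matrix), `classes` (factor), `lengths`.
#' @export
make_coefficient_dataset <- function(n_per_group, n_coef = 10L,
                                     effect_matrix = NULL,
                                     length_slopes = 0,
                                     interaction_slopes = NULL,
                                     length_mean = 30, length_sd = 2.5,
                                     noise_sd = 1, seed = 1L) {
  k <- length(n_per_group)
  gnames <- if (is.null(names(n_per_group))) paste0("G", seq_len(k))
            else names(n_per_group)
  n <- sum(n_per_group)
  if (is.null(effect_matrix)) effect_matrix <- matrix(0, k, n_coef)
  if (is.null(interaction_slopes)) interaction_slopes <- matrix(0, k, n_coef)
  length_slopes <- rep_len(length_slopes, n_coef)
  .with_seed(seed, {
    classes <- factor(rep(gnames, times = n_per_group), levels = gnames)
    lengths <- stats::rnorm(n, length_mean, length_sd)
    gi <- as.integer(classes)
    mu <- effect_matrix[gi, , drop = FALSE] +
      outer(lengths - length_mean, length_slopes) +
      interaction_slopes[gi, , drop = FALSE] * (lengths - length_mean)
    coeffs <- mu + matrix(stats::rnorm(n * n_coef, sd = noise_sd), n, n_coef)
    colnames(coeffs) <- paste0("C", seq_len(n_coef))
    list(coeffs = coeffs, classes = classes, lengths = lengths)
  })
}
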