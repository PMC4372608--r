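# Calibrated size descriptors, group mean shapes from wavelet
# reconstruction, and the per-angle variance partition (ICC).

#' Calibrated otolith size descriptors
#'
#' Computes, per active fish, on the (smoothed) raw outline: maximum Feret
#' length, width (maximal extent perpendicular to the Feret axis), polygon
#' perimeter and shoelace area. With a positive per-fish `cal` (pixels per
#' mm) lengths are in mm and areas in mm^2; otherwise pixel units are used
#' with a warning.
#'
#' @param store an `otoshape_project` (after [enrich_master_list()]; before
#'   that, all outlined fish are measured).
#' @param use_filter honor the active-record filter.
#' @return data.frame with columns `folder`, `picname`, `otolith.length`,
#'   `otolith.width`, `otolith.perimeter`, `otolith.area`.
#' @export
get_measurements <- function(store, use_filter = TRUE) {
  stopifnot(inherits(store, "otoshape_project"))
  if (!is.null(store$master)) {
    ml <- get_masterlist(store, use_filter)
    keys <- rownames(ml)
    cal <- if (store$capabilities$calibration && !is.null(ml$cal)) ml$cal
           else rep(NA_real_, length(keys))
  } else {
    keys <- names(store$outlines)
    km <- match(keys, oto_key(store$data$folder, store$data$picname))
    cal <- if (store$capabilities$calibration) store$data$cal[km] else rep(NA_real_, length(keys))
  }
  if (!length(keys)) stop("no outlined records to measure")
  if (anyNA(cal)) {
    warning("missing calibration for ", sum(is.na(cal)),
            " fish; measurements reported in pixel units for those")
  }
  bad <- !is.na(cal) & cal <= 0
  if (any(bad))
    stop("non-positive 'cal' for: ", paste(keys[bad], collapse = ", "))
  out <- data.frame(folder = dirname(keys), picname = basename(keys),
                    otolith.length = NA_real_, otolith.width = NA_real_,
                    otolith.perimeter = NA_real_, otolith.area = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(keys)) {
    xy <- as_outline_matrix(.analysis_outline(store, keys[i]))
    fer <- feret_diameter(xy)
    wd <- directional_extent(xy, fer$angle + pi / 2)
    per <- polygon_perimeter(xy)
    area <- abs(polygon_signed_area(xy))
    s <- if (is.na(cal[i])) 1 else cal[i]
    out$otolith.length[i] <- fer$length / s
    out$otolith.width[i] <- wd / s
    out$otolith.perimeter[i] <- per / s
    out$otolith.area[i] <- area / s^2
  }
  rownames(out) <- keys
  out
}

#' Per-group means of the size descriptors
#'
#' @param store an `otoshape_project` after [enrich_master_list()].
#' @param class_column grouping column in the master list (e.g. `"pop"`).
#' @param measurements optionally a precomputed [get_measurements()] table
#'   (must be aligned with the active master list).
#' @return data.frame, one row per non-empty group, with the mean of each
#'   size descriptor.
#' @export
group_means <- function(store, class_column,
                        measurements = get_measurements(store)) {
  ml <- get_masterlist(store)
  if (!class_column %in% names(ml))
    stop("class column '", class_column, "' not found")
  g <- factor(ml[[class_column]])
  empty <- levels(g)[tabulate(g, nlevels(g)) == 0L]
  if (length(empty)) {
    warning("empty group(s) omitted: ", paste(empty, collapse = ", "))
    g <- droplevels(g)
  }
  vars <- c("otolith.length", "otolith.width",
            "otolith.perimeter", "otolith.area")
  res <- do.call(rbind, lapply(split(measurements[, vars], g), colMeans))
  data.frame(group = rownames(res), res, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-group mean otolith shape from wavelet reconstruction
#'
#' Averages the 64 retained wavelet coefficients over the fish of each
#' group, reconstructs the mean radial profile, and converts it to a closed
#' outline about the origin. Because the transform is linear this equals the
#' coefficient vector of the group's mean profile.
#'
#' @param store an `otoshape_project` with wavelet coefficients and a
#'   master list.
#' @param class_column grouping column name.
#' @param use_std use the length-standardized coefficients? Only possible
#'   when no wavelet coefficient was screened out.
#' @return named list of outline matrices, one per non-empty group.
#' @export
mean_wavelet_shape <- function(store, class_column, use_std = FALSE) {
  m <- if (use_std) get_std_wavelet(store) else get_wavelet(store)
  if (use_std && ncol(m) != 64L)
    stop("standardized wavelet matrix has omitted coefficients; ",
         "mean shapes need the full 64")
  ml <- get_masterlist(store)
  g <- factor(ml[[class_column]])
  g <- droplevels(g)
  shapes <- lapply(levels(g), function(lv) {
    mu <- colMeans(m[g == lv, , drop = FALSE])
    profile_to_outline(wavelet_reconstruct(mu))
  })
  names(shapes) <- levels(g)
  shapes
}

#' Plot the per-group mean otolith shapes
#'
#' Draws the group mean shapes with the centroid cross and angle marks
#' (0, 90, 180, 270 degrees) of the polar coordinate system.
#'
#' @inheritParams mean_wavelet_shape
#' @param show_angle draw the angle labels.
#' @param ... line parameters passed to [graphics::lines()].
#' @return the shapes list, invisibly.
#' @export
plot_wavelet_shape <- function(store, class_column, use_std = FALSE,
                               show_angle = TRUE, ...) {
  shapes <- mean_wavelet_shape(store, class_column, use_std)
  rng <- range(unlist(shapes)) * 1.25
  graphics::plot(rng, rng, type = "n", asp = 1, xlab = "", ylab = "",
                 axes = FALSE)
  for (i in seq_along(shapes)) {
    xy <- shapes[[i]]
    graphics::lines(rbind(xy, xy[1, ]), col = i, ...)
  }
  graphics::points(0, 0, pch = 3, cex = 2)
  if (show_angle) {
    r <- max(abs(rng))
    graphics::text(c(r, 0, -r, 0) * 0.95, c(0, r, 0, -r) * 0.95,
                   labels = c("0", "90", "180", "270"))
  }
  graphics::legend("topright", legend = names(shapes),
                   col = seq_along(shapes), lty = 1, bty = "n")
  invisible(shapes)
}

#' One-way intraclass correlation (variance components)
#'
#' ICC = sigma2_among / (sigma2_among + sigma2_within) from a one-way
#' random-effects ANOVA with the unweighted-n0 correction for unequal group
#' sizes; negative among-group variance estimates are truncated at 0.
#'
#' @param y numeric response.
#' @param groups group labels.
#' @return ICC in `[0, 1]`.
#' @export
icc_oneway <- function(y, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("ICC needs at least 2 groups")
  fit <- stats::aov(y ~ g)
  ms <- stats::anova(fit)[["Mean Sq"]]
  n_i <- tabulate(g)
  n_i <- n_i[n_i > 0]
  N <- sum(n_i)
  k <- length(n_i)
  n0 <- (N - sum(n_i^2) / N) / (k - 1)
  s2a <- max(0, (ms[1] - ms[2]) / n0)
  s2w <- ms[2]
  if (s2a + s2w <= 0) return(0)
  s2a / (s2a + s2w)
}

#' Per-angle mean, spread and variance partition of wavelet coefficients
#'
#' For each detail coefficient at the requested wavelet level, computes the
#' mean and standard deviation over the active fish, the standard error,
#' and the intraclass correlation (among-group variance proportion) for the
#' grouping in `class_column`. Rows are ordered by the coefficient's centre
#' angle, so peaks localize where on the outline the groups differ.
#'
#' @param store an `otoshape_project` with (standardized) wavelet
#'   coefficients and a master list.
#' @param level detail level (default 5: 32 coefficients, one per 11.25
#'   degrees).
#' @param class_column grouping column name.
#' @param use_std use length-standardized coefficients (screened-out
#'   coefficients get NA rows, with a warning).
#' @return data.frame with columns `coef`, `angle`, `mean`, `sd`, `se`,
#'   `icc`.
#' @export
angle_variance_icc <- function(store, level = 5L, class_column,
                               use_std = TRUE) {
  if (level < 0L || level > 5L) stop("level must be in 0..5")
  amap <- wavelet_angle_map()
  idx <- which(amap$level == level)
  cols <- paste0("W", amap$index[idx])
  m <- if (use_std) get_std_wavelet(store) else get_wavelet(store)
  ml <- get_masterlist(store)
  g <- factor(ml[[class_column]])
  if (nlevels(droplevels(g)) < 2L) stop("ICC needs at least 2 groups")
  avail <- cols %in% colnames(m)
  if (!all(avail))
    warning(sum(!avail), " level-", level,
            " coefficient(s) were screened out; reported as NA")
  out <- data.frame(coef = cols, angle = amap$angle[idx],
                    mean = NA_real_, sd = NA_real_, se = NA_real_,
                    icc = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(cols)) {
    if (!avail[i]) next
    y <- m[, cols[i]]
    out$mean[i] <- mean(y)
    out$sd[i] <- stats::sd(y)
    out$se[i] <- out$sd[i] / sqrt(length(y))
    out$icc[i] <- icc_oneway(y, g)
  }
  out[order(out$angle), ]
}
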