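# Store-level outline operations: batch detection over the Fixed/ tree,
# overlay QC images, removal/re-detection, and batch smoothing.

# every eligible image under Fixed/: CSV records plus any discovered *.jpg
.eligible_images <- function(store) {
  fixed <- file.path(store$project_path, "Fixed")
  found <- list.files(fixed, pattern = "\\.jpe?g$", ignore.case = TRUE,
                      recursive = TRUE, full.names = FALSE)
  found_keys <- sub("\\.jpe?g$", "", found, ignore.case = TRUE)
  csv_keys <- oto_key(store$data$folder, store$data$picname)
  extra <- setdiff(found_keys, csv_keys)
  if (length(extra))
    warning("images under Fixed/ without metadata rows: ",
            paste(extra, collapse = ", "))
  missing <- setdiff(csv_keys, found_keys)
  if (length(missing))
    warning("metadata rows without images under Fixed/: ",
            paste(missing, collapse = ", "))
  keys <- union(intersect(csv_keys, found_keys), extra)
  paths <- file.path(fixed, paste0(keys, ".jpg"))
  alt <- !file.exists(paths)
  if (any(alt)) {
    # keep whatever extension was actually found
    idx <- match(keys[alt], found_keys)
    paths[alt] <- file.path(fixed, found[idx])
  }
  data.frame(key = keys, path = paths, stringsAsFactors = FALSE)
}

#' Detect otolith outlines for every image lacking one
#'
#' Reads each eligible image under `Fixed/<folder>/`, converts it to
#' grayscale, binarizes it at `threshold`, and traces the closed boundary of
#' the otolith component ([trace_contour()]). Only images without a stored
#' outline are processed, so removing a bad outline and re-running detects
#' just that fish. Per-image failures are logged and skipped, and summarized
#' at the end. With `write_overlay = TRUE` the traced outline is drawn in
#' red on the `Original/` image and written to `Original_with_outline/`.
#'
#' @param store an `otoshape_project`.
#' @param threshold intensity threshold in (0, 1); default 0.2.
#' @param write_overlay write QC overlay JPEGs (default FALSE).
#' @param seed_points optional named list `"FOLDER/PIC" = c(x, y)` giving an
#'   explicit seed pixel for images where the default (image centre /
#'   largest component) picks the wrong blob.
#' @return the store with outlines added.
#' @export
detect_outline <- function(store, threshold = 0.2, write_overlay = FALSE,
                           seed_points = NULL) {
  stopifnot(inherits(store, "otoshape_project"))
  imgs <- .eligible_images(store)
  todo <- imgs[!(imgs$key %in% names(store$outlines)), , drop = FALSE]
  failures <- character(0)
  overlay_root <- file.path(store$project_path, "Original_with_outline")
  for (i in seq_len(nrow(todo))) {
    key <- todo$key[i]
    res <- tryCatch({
      g <- read_gray(todo$path[i])
      bin <- binarize(g, threshold)
      outline <- trace_contour(bin, seed = seed_points[[key]])
      store$outlines[[key]] <- outline
      if (write_overlay) {
        orig_path <- file.path(store$project_path, "Original",
                               basename(dirname(todo$path[i])),
                               basename(todo$path[i]))
        if (!file.exists(orig_path)) orig_path <- todo$path[i]
        dir.create(file.path(overlay_root, dirname(key)),
                   recursive = TRUE, showWarnings = FALSE)
        write_overlay_image(orig_path, outline,
                            file.path(overlay_root, paste0(key, ".jpg")))
      }
      TRUE
    }, error = function(e) {
      failures <<- c(failures, paste0(key, ": ", conditionMessage(e)))
      FALSE
    })
  }
  store$threshold_used <- threshold
  if (length(failures))
    warning("outline detection failed for ", length(failures), " image(s):\n  ",
            paste(failures, collapse = "\n  "))
  message(nrow(todo) - length(failures), " outline(s) detected, ",
          length(store$outlines), " total")
  store
}

write_overlay_image <- function(orig_path, outline, out_path) {
  arr <- read_color(orig_path)
  h <- dim(arr)[1]; w <- dim(arr)[2]
  ok <- outline[, 2] >= 1 & outline[, 2] <= h & outline[, 1] >= 1 & outline[, 1] <= w
  idx <- cbind(outline[ok, 2], outline[ok, 1])
  arr[cbind(idx, 1L)] <- 1; arr[cbind(idx, 2L)] <- 0; arr[cbind(idx, 3L)] <- 0
  write_jpeg_raster(arr, out_path)
}

#' Remove one traced outline (and its derived coefficients)
#'
#' @param store an `otoshape_project`.
#' @param folder,picname the record key.
#' @return the store without that outline.
#' @export
remove_outline <- function(store, folder, picname) {
  stopifnot(inherits(store, "otoshape_project"))
  key <- oto_key(folder, picname)
  if (!key %in% names(store$outlines))
    stop("no outline stored for ", key)
  store$outlines[[key]] <- NULL
  store$outlines_smoothed[[key]] <- NULL
  for (what in c("wavelet", "fourier")) {
    for (slot in c("coef", "std")) {
      m <- store[[slot]][[what]]
      if (!is.null(m) && key %in% rownames(m))
        store[[slot]][[what]] <- m[rownames(m) != key, , drop = FALSE]
    }
  }
  if (!is.null(store$master) && key %in% rownames(store$master)) {
    keep <- rownames(store$master) != key
    store$master <- store$master[keep, , drop = FALSE]
    store$filter <- store$filter[keep]
  }
  store
}

#' Display the original image with its traced outline
#'
#' Returns (and optionally plots) the `Original/` image with the stored
#' outline recolored in red.
#'
#' @param store an `otoshape_project`.
#' @param folder,picname the record key.
#' @param plot draw the overlay on the current graphics device?
#' @return the overlay raster array `[y, x, 3]`, invisibly.
#' @export
show_original_with_outline <- function(store, folder, picname, plot = TRUE) {
  stopifnot(inherits(store, "otoshape_project"))
  key <- oto_key(folder, picname)
  outline <- store$outlines[[key]]
  if (is.null(outline)) stop("no outline stored for ", key)
  path <- file.path(store$project_path, "Original", folder,
                    paste0(picname, ".jpg"))
  if (!file.exists(path))
    path <- file.path(store$project_path, "Fixed", folder,
                      paste0(picname, ".jpg"))
  if (!file.exists(path)) stop("no image found for ", key)
  arr <- read_color(path)
  idx <- cbind(outline[, 2], outline[, 1])
  arr[cbind(idx, 1L)] <- 1; arr[cbind(idx, 2L)] <- 0; arr[cbind(idx, 3L)] <- 0
  if (plot) {
    op <- graphics::par(mar = c(0, 0, 0, 0)); on.exit(graphics::par(op))
    graphics::plot(c(0, ncol(arr)), c(0, nrow(arr)), type = "n", asp = 1,
                   axes = FALSE, xlab = "", ylab = "")
    graphics::rasterImage(arr, 0, 0, ncol(arr), nrow(arr))
  }
  invisible(arr)
}

#' Smooth all stored outlines
#'
#' Applies the (1,2,1)/4 weighted moving average of [smooth_outline()] to
#' every traced outline; `iterations` is the maximum number of passes.
#' Downstream coefficient generation and measurements use the smoothed
#' outlines once this has run.
#'
#' @param store an `otoshape_project` with outlines.
#' @param iterations smoothing passes (default 100, a strong polish for
#'   pixel-resolution contours).
#' @return the store with smoothed outlines.
#' @export
smooth_outlines <- function(store, iterations = 100L) {
  stopifnot(inherits(store, "otoshape_project"))
  if (!length(store$outlines)) stop("no outlines to smooth")
  store$outlines_smoothed <- lapply(store$outlines, smooth_outline,
                                    iterations = iterations)
  store$smooth_iterations <- as.integer(iterations)
  store
}

# the outline used for analysis: smoothed when available
.analysis_outline <- function(store, key) {
  o <- store$outlines_smoothed[[key]]
  if (is.null(o)) o <- store$outlines[[key]]
  o
}

#' Generate wavelet and Fourier shape coefficients for every outline
#'
#' For each outlined fish the (smoothed) contour is normalized for
#' position, rotation and size ([normalize_outline()]); its 1024-point
#' equidistant-angle radial profile yields 64 wavelet coefficients
#' ([wavelet_coefficients()]), and the normalized contour yields 45
#' normalized elliptic Fourier coefficients (12 harmonics,
#' [normalize_efd()]). Already-computed rows are kept; only new outlines
#' are processed. Per-fish failures (e.g. a centroid falling outside a
#' pathological outline) are skipped with a named warning.
#'
#' @param store an `otoshape_project` with outlines.
#' @param harmonics Fourier harmonics (default 12 giving 45 coefficients).
#' @param n_angles radial-profile length (default 1024 = 2^10).
#' @return the store with `$coef$wavelet` and `$coef$fourier` filled.
#' @export
generate_shape_coefficients <- function(store, harmonics = 12L,
                                        n_angles = 1024L) {
  stopifnot(inherits(store, "otoshape_project"))
  keys <- names(store$outlines)
  if (!length(keys)) stop("no outlines present; run detect_outline() first")
  done <- rownames(store$coef$wavelet)
  todo <- setdiff(keys, done)
  wl <- list(); fl <- list()
  failures <- character(0)
  for (key in todo) {
    res <- tryCatch({
      norm <- normalize_outline(.analysis_outline(store, key), raster = TRUE)
      prof <- radial_profile(norm, n_angles)
      wl[[key]] <- as.numeric(wavelet_coefficients(prof))
      fl[[key]] <- as.numeric(normalize_efd(efourier(norm, harmonics)))
      TRUE
    }, error = function(e) {
      failures <<- c(failures, paste0(key, ": ", conditionMessage(e)))
      FALSE
    })
  }
  if (length(failures))
    warning("coefficient generation failed for:\n  ",
            paste(failures, collapse = "\n  "))
  if (length(wl)) {
    wnew <- do.call(rbind, wl)
    colnames(wnew) <- paste0("W", seq_len(ncol(wnew)))
    fnew <- do.call(rbind, fl)
    colnames(fnew) <- paste0("F", seq_len(ncol(fnew)))
    store$coef$wavelet <- rbind(store$coef$wavelet, wnew)
    store$coef$fourier <- rbind(store$coef$fourier, fnew)
  }
  if (is.null(store$coef$wavelet))
    stop("coefficient generation produced no rows")
  store
}
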