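# Binarization and contour tracing, plus the store-level detect / remove /
# re-detect semantics on a synthetic image project.

test_that("binarization thresholds strictly and flags degenerate cases", {
  img <- matrix(0.05, 60, 80)
  img[20:40, 30:50] <- 0.8
  b1 <- suppressWarnings(binarize(img, 0.2))
  expect_identical(sum(b1), 21L * 21L)
  # any threshold between the two modes gives the same foreground
  expect_identical(binarize(img, 0.3), b1)
  expect_error(binarize(matrix(0, 10, 10), 0.2), "empty foreground")
  expect_error(binarize(img, 0), "threshold")
  border <- matrix(0.9, 10, 10)
  expect_warning(binarize(border, 0.2), "border")
})

test_that("foreground shrinks monotonically with the threshold", {
  set.seed(5)
  img <- matrix(runif(2500), 50, 50)
  f1 <- suppressWarnings(binarize(img, 0.3))
  f2 <- suppressWarnings(binarize(img, 0.6))
  expect_true(all(f1[f2]))  # f2 subset of f1
})

test_that("tracing a filled square visits its 4s - 4 boundary pixels", {
  for (s in c(10L, 25L)) {
    bin <- matrix(FALSE, 60, 60)
    bin[20:(20 + s - 1L), 15:(15 + s - 1L)] <- TRUE
    o <- trace_contour(bin)
    expect_identical(nrow(o), 4L * s - 4L)
    # closed 8-connected cycle
    d <- rbind(o[-1, ] - o[-nrow(o), ], o[1, ] - o[nrow(o), ])
    expect_true(all(abs(d) <= 1L) && !any(d[, 1] == 0L & d[, 2] == 0L))
  }
})

test_that("traced disk area agrees with the pixel-count oracle", {
  bin <- raster_disk(260, 260, 130, 130, 100)
  o <- trace_contour(bin)
  area <- abs(otoshape:::polygon_signed_area(o))
  expect_lt(abs(area / sum(bin) - 1), 0.02)
  expect_lt(abs(area / (pi * 100^2) - 1), 0.02)
})

test_that("shoelace area tracks pixel counts on random star blobs", {
  set.seed(17)
  for (rep in 1:5) {
    spec <- blob_spec(base_radius = runif(1, 40, 70),
                      amplitudes = c(`2` = runif(1, 0, 0.2),
                                     `3` = runif(1, 0, 0.1)),
                      phases = runif(2, 0, 2 * pi),
                      noise_sd = 0, width = 220L, height = 220L)
    img <- render_blob(spec, seed = rep)
    bin <- binarize(img, 0.2)
    o <- trace_contour(bin)
    expect_lt(abs(abs(otoshape:::polygon_signed_area(o)) / sum(bin) - 1), 0.05)
  }
})

test_that("the seed selects the component; specks and misses error", {
  bin <- raster_disk(120, 200, 60, 60, 30) | raster_disk(120, 200, 150, 60, 12)
  big <- trace_contour(bin)                      # default: largest blob
  small <- trace_contour(bin, seed = c(150, 60)) # explicit seed: small blob
  expect_gt(abs(otoshape:::polygon_signed_area(big)),
            abs(otoshape:::polygon_signed_area(small)))
  expect_true(all(small[, 1] > 120))
  # seed near (not on) the small blob still finds it
  near <- trace_contour(bin, seed = c(170, 60))
  expect_equal(dim(near), dim(small))
  expect_error(trace_contour(bin, seed = c(195, 115), search_radius = 3),
               "no foreground")
  speck <- matrix(FALSE, 40, 40); speck[20, 20] <- TRUE; speck[20, 21] <- TRUE
  expect_error(trace_contour(speck), "speck")
})

test_that("detect / remove / re-detect process exactly the missing outlines", {
  env <- tiny_project()
  s <- env$store
  n0 <- length(s$outlines)
  expect_identical(n0, 18L)
  key_outline <- s$outlines[["IC/403_2"]]
  s2 <- remove_outline(s, "IC", "403_2")
  expect_false("IC/403_2" %in% names(s2$outlines))
  expect_false("IC/403_2" %in% rownames(s2$coef$wavelet))
  expect_error(remove_outline(s2, "IC", "403_2"), "no outline")
  expect_message(s3 <- detect_outline(s2, threshold = 0.2),
                 "1 outline\\(s\\) detected")
  expect_identical(length(s3$outlines), n0)
  expect_identical(s3$outlines[["IC/403_2"]], key_outline)
  # untouched outlines are not recomputed (identical objects)
  expect_identical(s3$outlines[["NO/404_1"]], s$outlines[["NO/404_1"]])
})

test_that("coefficients grow incrementally after re-detection", {
  env <- tiny_project()
  s <- env$store
  s2 <- remove_outline(s, "SC", "405_3")
  expect_identical(nrow(s2$coef$wavelet), 17L)
  s2 <- suppressMessages(detect_outline(s2, threshold = 0.2))
  s2 <- smooth_outlines(s2, 100L)
  s2 <- suppressMessages(generate_shape_coefficients(s2))
  expect_identical(nrow(s2$coef$wavelet), 18L)
  expect_identical(ncol(s2$coef$wavelet), 64L)
  expect_identical(ncol(s2$coef$fourier), 45L)
  shared <- setdiff(rownames(s$coef$wavelet), "SC/405_3")
  expect_identical(s2$coef$wavelet[shared, ], s$coef$wavelet[shared, ])
  expect_equal(s2$coef$wavelet["SC/405_3", ], s$coef$wavelet["SC/405_3", ],
               tolerance = 1e-12)
})

test_that("a corrupt image is logged and skipped, not fatal", {
  dir <- file.path(tempdir(), "otoshape-corrupt")
  unlink(dir, recursive = TRUE)
  make_project(dir, n_per_group = c(IC = 3L), width = 240L, height = 200L,
               length_model = list(mean = 30, sd = 2, radius_per_cm = 1.8,
                                   elong_per_cm = 0),
               seed = 5L)
  writeLines("not a jpeg", file.path(dir, "Fixed", "IC", "403_2.jpg"))
  s <- load_project(dir)
  expect_warning(s <- detect_outline(s, 0.2), "403_2")
  expect_identical(length(s$outlines), 2L)
})

test_that("overlays recolor exactly the traced outline pixels", {
  env <- tiny_project()
  s <- env$store
  arr <- show_original_with_outline(s, "IC", "403_1", plot = FALSE)
  o <- s$outlines[["IC/403_1"]]
  idx <- cbind(o[, 2], o[, 1])
  expect_true(all(arr[cbind(idx, 1L)] == 1))
  expect_true(all(arr[cbind(idx, 2L)] == 0))
  s2 <- remove_outline(s, "IC", "403_1")
  expect_error(show_original_with_outline(s2, "IC", "403_1"), "no outline")
  # overlay files were written at detection time when requested
  dir2 <- file.path(tempdir(), "otoshape-overlay")
  unlink(dir2, recursive = TRUE)
  make_project(dir2, n_per_group = c(IC = 2L), width = 240L, height = 200L,
               length_model = list(mean = 30, sd = 2, radius_per_cm = 1.8,
                                   elong_per_cm = 0),
               seed = 6L)
  so <- load_project(dir2)
  so <- suppressMessages(detect_outline(so, 0.2, write_overlay = TRUE))
  expect_true(file.exists(file.path(dir2, "Original_with_outline",
                                    "IC", "403_1.jpg")))
})

test_that("reversing traversal direction leaves downstream coefficients unchanged", {
  env <- tiny_project()
  s <- env$store
  o <- s$outlines[["NO/404_2"]]
  orev <- o[rev(seq_len(nrow(o))), ]
  norm_fwd <- normalize_outline(o, raster = TRUE)
  norm_rev <- normalize_outline(orev, raster = TRUE)
  expect_equal(as.numeric(wavelet_coefficients(radial_profile(norm_rev, 1024))),
               as.numeric(wavelet_coefficients(radial_profile(norm_fwd, 1024))),
               tolerance = 1e-6)
  expect_equal(as.numeric(normalize_efd(efourier(norm_rev, 12))),
               as.numeric(normalize_efd(efourier(norm_fwd, 12))),
               tolerance = 1e-6)
})
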