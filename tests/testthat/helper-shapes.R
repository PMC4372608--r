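# Analytic shapes, fake stores and a session-cached tiny synthetic project
# shared across test files. Everything is generated in code at test time.

make_circle <- function(n = 512, r = 1, center = c(0, 0)) {
  tt <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = center[1] + r * cos(tt), y = center[2] + r * sin(tt))
}

make_ellipse <- function(n = 512, a = 2, b = 1, rot = 0, center = c(0, 0)) {
  tt <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  xy <- cbind(x = a * cos(tt), y = b * sin(tt))
  xy <- xy %*% t(matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2))
  colnames(xy) <- c("x", "y")
  sweep(xy, 2, -center)
}

# axis-aligned square traversed counter-clockwise, many points per side,
# all four corners included exactly once
make_square <- function(side = 2, pts_per_side = 64) {
  s <- side / 2
  up <- seq(-s, s, length.out = pts_per_side + 1)[-(pts_per_side + 1)]
  dn <- seq(s, -s, length.out = pts_per_side + 1)[-(pts_per_side + 1)]
  rbind(cbind(x = up, y = -s), cbind(x = s, y = up),
        cbind(x = dn, y = s), cbind(x = -s, y = dn))
}

# binary raster with a filled disk / square / custom radial blob
raster_disk <- function(h, w, cx, cy, r) {
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  (xs - cx)^2 + (ys - cy)^2 < r^2
}

# minimal project container around ready-made outlines / coefficients, for
# testing measurement, ICC and mean-shape code without touching the disk
fake_store <- function(outlines = list(), data = NULL,
                       wavelet = NULL, fourier = NULL, master = NULL) {
  keys <- names(outlines)
  if (is.null(data)) {
    if (length(keys)) {
      data <- data.frame(folder = dirname(keys), picname = basename(keys),
                         cal = 100, stringsAsFactors = FALSE)
    } else {
      data <- data.frame(folder = character(), picname = character(),
                         cal = numeric())
    }
  }
  st <- structure(list(
    project_path = tempdir(), csv_name = "FISH.csv", data = data,
    outlines = outlines, outlines_smoothed = list(),
    smooth_iterations = 0L, threshold_used = NA_real_,
    coef = list(wavelet = wavelet, fourier = fourier),
    std = list(wavelet = NULL, fourier = NULL, info = list()),
    master = master,
    filter = if (is.null(master)) NULL else rep(TRUE, nrow(master)),
    capabilities = list(standardization = TRUE, calibration = "cal" %in% names(data)),
    version = 1L), class = "otoshape_project")
  st
}

# store whose wavelet matrix comes from analytic radial profiles, with a
# master list; `profiles` is a named list of length-1024 radius vectors
store_from_profiles <- function(profiles, pop) {
  w <- t(vapply(profiles, function(p)
    as.numeric(wavelet_coefficients(p)), numeric(64)))
  colnames(w) <- paste0("W", 1:64)
  rownames(w) <- names(profiles)
  master <- data.frame(folder = dirname(names(profiles)),
                       picname = basename(names(profiles)),
                       pop = pop, stringsAsFactors = FALSE)
  rownames(master) <- names(profiles)
  fake_store(wavelet = w, master = master)
}

# tiny synthetic image project, built once per test session
.test_proj_env <- new.env()
tiny_project <- function() {
  if (!is.null(.test_proj_env$store)) return(.test_proj_env)
  dir <- file.path(tempdir(), "otoshape-test-project")
  unlink(dir, recursive = TRUE)
  make_project(dir, n_per_group = c(IC = 6L, NO = 6L, SC = 6L),
               width = 400L, height = 300L,
               length_model = list(mean = 30, sd = 2.5,
                                   radius_per_cm = 2.8,
                                   elong_per_cm = 0.004),
               seed = 421L)
  store <- load_project(dir)
  store <- suppressMessages(detect_outline(store, threshold = 0.2))
  store <- smooth_outlines(store, 100L)
  store <- suppressMessages(generate_shape_coefficients(store))
  store <- suppressMessages(enrich_master_list(store))
  .test_proj_env$dir <- dir
  .test_proj_env$store <- store
  .test_proj_env
}
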