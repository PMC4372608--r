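# Calibrated size descriptors, group means, mean shapes, per-angle ICC.

test_that("square and ellipse measurements match their geometry", {
  sq <- make_square(200, 50)  # side 200 px
  st <- fake_store(outlines = list("IC/1_1" = sq),
                   data = data.frame(folder = "IC", picname = "1_1",
                                     cal = 100))
  m <- get_measurements(st)
  expect_equal(m$otolith.length, 2 * sqrt(2), tolerance = 1e-9)
  expect_equal(m$otolith.width, 2 * sqrt(2), tolerance = 1e-9)
  expect_equal(m$otolith.perimeter, 8, tolerance = 1e-9)
  expect_equal(m$otolith.area, 4, tolerance = 1e-9)

  ell <- make_ellipse(2000, a = 300, b = 150)
  st2 <- fake_store(outlines = list("IC/1_1" = ell),
                    data = data.frame(folder = "IC", picname = "1_1",
                                      cal = 100))
  m2 <- get_measurements(st2)
  expect_lt(abs(m2$otolith.area / (pi * 3 * 1.5) - 1), 0.01)
  expect_equal(m2$otolith.length, 6, tolerance = 1e-3)
  expect_equal(m2$otolith.width, 3, tolerance = 1e-3)
})

test_that("measurements scale as cal^-1 and cal^-2; bad cal errors", {
  ell <- make_ellipse(1200, a = 200, b = 120)
  st1 <- fake_store(outlines = list("IC/1_1" = ell),
                    data = data.frame(folder = "IC", picname = "1_1",
                                      cal = 100))
  st2 <- fake_store(outlines = list("IC/1_1" = ell),
                    data = data.frame(folder = "IC", picname = "1_1",
                                      cal = 200))
  m1 <- get_measurements(st1); m2 <- get_measurements(st2)
  expect_equal(m2$otolith.area, m1$otolith.area / 4, tolerance = 1e-12)
  expect_equal(m2$otolith.length, m1$otolith.length / 2, tolerance = 1e-12)
  expect_equal(m2$otolith.perimeter, m1$otolith.perimeter / 2,
               tolerance = 1e-12)
  bad <- fake_store(outlines = list("IC/1_1" = ell),
                    data = data.frame(folder = "IC", picname = "1_1",
                                      cal = -5))
  expect_error(get_measurements(bad), "IC/1_1")
  # isoperimetric sanity on a real traced outline
  env <- tiny_project()
  m <- get_measurements(env$store)
  expect_true(all(m$otolith.perimeter^2 >= 4 * pi * m$otolith.area))
  expect_true(all(m$otolith.length >= m$otolith.width))
})

test_that("Feret length equals the brute-force maximum pairwise distance", {
  set.seed(31)
  for (rep in 1:5) {
    prof <- 1 + 0.25 * cos(2 * (2 * pi * (0:199) / 200) + runif(1, 0, pi)) +
      0.05 * rnorm(200)
    xy <- profile_to_outline(prof)
    fer <- otoshape:::feret_diameter(xy)
    d2 <- as.matrix(stats::dist(xy))
    expect_equal(fer$length, max(d2), tolerance = 1e-12)
  }
})

test_that("group means honor groups and the filter", {
  keys <- c("A/1", "A/2", "B/1")
  st <- store_from_profiles(
    setNames(lapply(c(1, 1.2, 1.5), function(r) rep(r, 1024)), keys),
    pop = c("A", "A", "B"))
  st$outlines <- setNames(lapply(c(1, 3, 5), function(a)
    make_circle(400, r = sqrt(a / pi) * 100)), keys)
  st$master$cal <- 100
  m <- get_measurements(st)
  gm <- group_means(st, "pop", m)
  expect_equal(gm$otolith.area, c(2, 5), tolerance = 0.01)
  st2 <- set_filter(st, c(TRUE, TRUE, FALSE))
  gm2 <- group_means(st2, "pop", get_measurements(st2))
  expect_identical(gm2$group, "A")
  st3 <- set_filter(st, c(TRUE, FALSE, FALSE))
  gm3 <- group_means(st3, "pop", get_measurements(st3))
  expect_equal(gm3$otolith.area, 1, tolerance = 0.01)
})

test_that("mean wavelet shapes: circles, linearity, single-fish groups", {
  prof_circ <- rep(1.3, 1024)
  st <- store_from_profiles(list("A/1" = prof_circ, "A/2" = prof_circ,
                                 "B/1" = prof_circ),
                            pop = c("A", "A", "B"))
  shapes <- mean_wavelet_shape(st, "pop")
  for (sh in shapes) {
    r <- sqrt(rowSums(sh^2))
    expect_equal(r, rep(1.3, length(r)), tolerance = 1e-6)
  }
  # linearity: group mean shape equals reconstruction of the mean profile
  set.seed(7)
  profs <- list("A/1" = 1 + 0.1 * rnorm(1024), "A/2" = 1 + 0.1 * rnorm(1024))
  st2 <- store_from_profiles(profs, pop = c("A", "A"))
  sh <- mean_wavelet_shape(st2, "pop")$A
  mean_prof <- (profs[[1]] + profs[[2]]) / 2
  direct <- profile_to_outline(wavelet_reconstruct(
    wavelet_coefficients(mean_prof)))
  expect_equal(sh, direct, tolerance = 1e-9)
  # a single-fish group reproduces that fish's own reconstruction
  st3 <- store_from_profiles(profs, pop = c("A", "B"))
  sh3 <- mean_wavelet_shape(st3, "pop")$B
  own <- profile_to_outline(wavelet_reconstruct(
    wavelet_coefficients(profs[[2]])))
  expect_equal(sh3, own, tolerance = 1e-12)
})

test_that("group mean shapes localize a planted difference in angle", {
  th <- 360 * (0:1023) / 1024
  bump <- 0.15 * exp(-((th - 10) / 6)^2)  # bump centred at 10 degrees
  profs <- c(
    setNames(lapply(1:5, function(i) rep(1 + 0.002 * i, 1024)),
             paste0("A/", 1:5)),
    setNames(lapply(1:5, function(i) rep(1 + 0.002 * i, 1024) + bump),
             paste0("B/", 1:5)))
  st <- store_from_profiles(profs, pop = rep(c("A", "B"), each = 5))
  shapes <- mean_wavelet_shape(st, "pop")
  ra <- sqrt(rowSums(shapes$A^2)); rb <- sqrt(rowSums(shapes$B^2))
  dif <- abs(rb - ra)
  ang <- 360 * (seq_along(dif) - 1) / length(dif)
  expect_lt(abs(ang[which.max(dif)] - 10), 15)
  away <- dif[abs(((ang - 10 + 180) %% 360) - 180) > 40]
  expect_lt(max(away), max(dif) / 4)
})

test_that("ICC estimates variance partition and its invariances", {
  set.seed(12)
  y <- rnorm(60)
  g <- rep(c("a", "b", "c"), each = 20)
  i0 <- icc_oneway(y, g)
  expect_equal(icc_oneway(y + 100, g), i0, tolerance = 1e-9)
  expect_equal(icc_oneway(y * 7, g), i0, tolerance = 1e-12)
  expect_gte(i0, 0); expect_lte(i0, 1)
  expect_error(icc_oneway(y, rep("a", 60)), "2 groups")
  # strong separation
  y2 <- c(rnorm(30), rnorm(30) + 10)
  expect_gt(icc_oneway(y2, rep(c("a", "b"), each = 30)), 0.9)
})

test_that("null ICC stays small, planted ICC is found at its angle", {
  set.seed(99)
  null_icc <- replicate(200, icc_oneway(rnorm(100), rep(c("a", "b"), 50)))
  expect_lt(unname(quantile(null_icc, 0.95)), 0.15)
  # planted separation at one level-5 coefficient of a fake store
  n <- 50
  w <- matrix(rnorm(2 * n * 64), 2 * n, 64)
  colnames(w) <- paste0("W", 1:64)
  target <- 40  # a level-5 column (33..64)
  w[(n + 1):(2 * n), target] <- w[(n + 1):(2 * n), target] + 10
  keys <- paste0(rep(c("A", "B"), each = n), "/", rep(1:n, 2))
  rownames(w) <- keys
  master <- data.frame(folder = dirname(keys), picname = basename(keys),
                       pop = rep(c("A", "B"), each = n))
  rownames(master) <- keys
  st <- fake_store(wavelet = w, master = master)
  tab <- angle_variance_icc(st, level = 5, class_column = "pop",
                            use_std = FALSE)
  expect_identical(nrow(tab), 32L)
  expect_equal(diff(sort(tab$angle)), rep(360 / 32, 31), tolerance = 1e-9)
  amap <- wavelet_angle_map()
  target_angle <- amap$angle[amap$index == target]
  expect_gt(tab$icc[tab$angle == target_angle], 0.9)
  expect_lt(max(tab$icc[tab$angle != target_angle]), 0.3)
})
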