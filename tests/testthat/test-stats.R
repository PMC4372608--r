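# Constrained ordination, permutation ANOVA, cluster summaries, LDA error.

test_that("CAP yields groups-1 non-negative ordered axes with unit eig ratio", {
  d <- make_coefficient_dataset(c(15, 15, 15), n_coef = 6,
                                effect_matrix = rbind(c(2, rep(0, 5)),
                                                      c(0, 2, rep(0, 4)),
                                                      rep(0, 6)),
                                seed = 10)
  res <- cap(d$coeffs, d$classes)
  expect_length(res$eigenvalues, 2L)
  expect_true(all(diff(res$eigenvalues) <= 0))
  expect_true(all(res$eigenvalues >= 0))
  expect_equal(sum(res$eig_ratio), 1, tolerance = 1e-9)
  expect_identical(nrow(res$site_scores), 45L)
  few <- c(1L, 2L, 16L, 17L, 40L)  # 5 fish from 3 groups, 6 coefficients
  expect_error(cap(d$coeffs[few, ], d$classes[few]), "larger than")
  expect_error(cap(d$coeffs, rep("A", 45)), "2 groups")
})

test_that("CAP equals the least-squares projection oracle on a toy matrix", {
  set.seed(2)
  X <- matrix(rnorm(40), 10, 4)
  g <- factor(rep(c("a", "b"), each = 5))
  res <- cap(X, g)
  # brute force: regress centred X on group indicators, eigen-decompose fit
  Xc <- scale(X, scale = FALSE)
  G <- model.matrix(~g)
  H <- G %*% solve(crossprod(G)) %*% t(G)
  fitted <- H %*% Xc
  ev <- eigen(crossprod(fitted) / (nrow(X) - 1))$values
  expect_equal(res$eigenvalues, ev[seq_along(res$eigenvalues)],
               tolerance = 1e-9)
})

test_that("a large planted shift separates groups on the first axis", {
  d <- make_coefficient_dataset(c(20, 20), n_coef = 5,
                                effect_matrix = rbind(c(8, rep(0, 4)),
                                                      rep(0, 5)),
                                seed = 11)
  res <- cap(d$coeffs, d$classes)
  s1 <- res$site_scores[, 1]
  expect_true(max(s1[d$classes == levels(d$classes)[1]]) <
                min(s1[d$classes == levels(d$classes)[2]]) ||
              min(s1[d$classes == levels(d$classes)[1]]) >
                max(s1[d$classes == levels(d$classes)[2]]))
  # permuting labels always lowers the constrained-variance sum
  obs <- sum(res$eigenvalues)
  set.seed(1)
  perm <- replicate(20, sum(cap(d$coeffs, sample(d$classes))$eigenvalues))
  expect_true(all(perm < obs))
})

test_that("permutation ANOVA partitions variance like the vegan oracle", {
  d <- make_coefficient_dataset(c(12, 12, 12), n_coef = 4,
                                effect_matrix = rbind(c(1.5, 0, 0, 0),
                                                      c(0, 1.5, 0, 0),
                                                      rep(0, 4)),
                                seed = 12)
  res <- permutation_anova(d$coeffs, d$classes, permutations = 99, seed = 1)
  expect_identical(res$model_df, 2L)
  expect_identical(res$residual_df, 33L)
  oracle <- vegan::adonis2(d$coeffs ~ grp,
                           data = data.frame(grp = d$classes),
                           method = "euclidean", permutations = 99)
  expect_equal(res$pseudo_F, oracle$F[1], tolerance = 1e-9)
  expect_equal(res$model_ss, oracle$SumOfSqs[1], tolerance = 1e-9)
  expect_equal(res$residual_ss, oracle$SumOfSqs[2], tolerance = 1e-9)
})

test_that("the permutation p-value is calibrated under the null", {
  rejections <- 0L
  reps <- 200L
  for (r in seq_len(reps)) {
    d <- make_coefficient_dataset(c(15, 15), n_coef = 3, seed = 5000 + r)
    res <- permutation_anova(d$coeffs, d$classes, permutations = 99,
                             seed = r)
    if (res$p <= 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / reps
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / reps)
  expect_gte(rate, ci[1] - 0.01)
  expect_lte(rate, ci[2] + 0.01)
})

test_that("p is invariant to relabeling and floors at 1/(P+1) for separated groups", {
  d <- make_coefficient_dataset(c(20, 20), n_coef = 4,
                                effect_matrix = rbind(c(10, 0, 0, 0),
                                                      rep(0, 4)),
                                seed = 13)
  r1 <- permutation_anova(d$coeffs, d$classes, permutations = 199, seed = 7)
  relabeled <- factor(ifelse(d$classes == levels(d$classes)[1], "ZZ", "AA"))
  r2 <- permutation_anova(d$coeffs, relabeled, permutations = 199, seed = 7)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$pseudo_F, r2$pseudo_F)
  expect_equal(r1$p, 1 / 200)
  expect_error(permutation_anova(d$coeffs, d$classes, permutations = 0),
               "permutations")
})

test_that("cluster plot data summarizes means and standard errors", {
  d <- make_coefficient_dataset(c(10, 10, 10), n_coef = 4,
                                effect_matrix = rbind(c(3, 0, 0, 0),
                                                      c(0, 3, 0, 0),
                                                      rep(0, 4)),
                                seed = 14)
  res <- cap(d$coeffs, d$classes)
  cl <- cluster_plot_data(res)
  expect_identical(nrow(cl), 3L)
  expect_match(attr(cl, "axis_labels")[1], "^CAP1 \\([0-9.]+%\\)$")
  # duplicating every fish keeps means, divides SE by sqrt(2)
  d2 <- list(coeffs = rbind(d$coeffs, d$coeffs),
             classes = factor(c(as.character(d$classes),
                                as.character(d$classes))))
  res2 <- cap(d2$coeffs, d2$classes)
  cl2 <- cluster_plot_data(res2)
  # site scores carry an n-dependent overall scale and a sign ambiguity;
  # compare the scale-free spread-to-separation ratio instead. With the
  # sample sd, duplicating n points shrinks the SE by exactly
  # sqrt((n-1)/(2n-1)) * sqrt(2)/sqrt(2) -> factor sqrt(2(n-1)/(2n-1)) of
  # the naive 1/sqrt(2); both coincide as n grows
  sep <- which(abs(cl$mean1) > 10 * cl$se1)
  n_g <- cl$n[sep]
  expect_equal(cl2$se1[sep] / abs(cl2$mean1[sep]),
               (cl$se1[sep] / abs(cl$mean1[sep])) *
                 sqrt((n_g - 1) / (2 * n_g - 1)),
               tolerance = 1e-6)
  # single fish per group: zero-width intervals
  one <- make_coefficient_dataset(c(1, 1, 1), n_coef = 2, seed = 15)
  res3 <- suppressMessages(suppressWarnings(cap(one$coeffs, one$classes)))
  cl3 <- cluster_plot_data(res3)
  expect_identical(cl3$se1, rep(0, 3))
})

test_that("LDA error: separable zero, chance-level half, LOO matches the oracle", {
  sep <- make_coefficient_dataset(c(30, 30), n_coef = 3,
                                  effect_matrix = rbind(c(10, 0, 0),
                                                        rep(0, 3)),
                                  seed = 16)
  expect_identical(lda_error(sep$coeffs, sep$classes, "cv", folds = 10,
                             seed = 1)$error_rate, 0)
  same <- make_coefficient_dataset(c(50, 50), n_coef = 4, seed = 17)
  e <- lda_error(same$coeffs, same$classes, "cv", folds = 10, seed = 2)
  expect_gt(e$error_rate, 0.4)
  expect_lt(e$error_rate, 0.6)
  # leave-one-out equals an explicit loop
  d <- make_coefficient_dataset(c(12, 12), n_coef = 3,
                                effect_matrix = rbind(c(1.2, 0, 0),
                                                      rep(0, 3)),
                                seed = 18)
  n <- nrow(d$coeffs)
  loo <- lda_error(d$coeffs, d$classes, "cv", folds = n)$error_rate
  wrong <- 0L
  for (i in seq_len(n)) {
    fit <- MASS::lda(d$coeffs[-i, ], grouping = d$classes[-i])
    pred <- predict(fit, d$coeffs[i, , drop = FALSE])$class
    if (pred != d$classes[i]) wrong <- wrong + 1L
  }
  expect_identical(loo, wrong / n)
})

test_that("bootstrap error estimators behave sensibly", {
  d <- make_coefficient_dataset(c(40, 40), n_coef = 4,
                                effect_matrix = rbind(c(2, 0, 0, 0),
                                                      rep(0, 4)),
                                seed = 19)
  b <- lda_error(d$coeffs, d$classes, "boot", reps = 50, seed = 3)
  expect_gte(b$error_rate, 0); expect_lte(b$error_rate, 1)
  b632 <- lda_error(d$coeffs, d$classes, "boot632", reps = 50, seed = 3)
  # 0.632 correction pulls toward the (lower) apparent error
  expect_lte(b632$error_rate, b$error_rate + 1e-12)
  # determinism under a fixed seed
  b2 <- lda_error(d$coeffs, d$classes, "boot", reps = 50, seed = 3)
  expect_identical(b$error_rate, b2$error_rate)
})

test_that("a Mahalanobis-1.6 separation classifies in the 70-85% band", {
  accs <- vapply(1:20, function(sd) {
    d <- make_coefficient_dataset(c(65, 65), n_coef = 6,
                                  effect_matrix = rbind(
                                    c(1.6, rep(0, 5)), rep(0, 6)),
                                  noise_sd = 1, seed = 700 + sd)
    1 - lda_error(d$coeffs, d$classes, "cv", folds = 10,
                  seed = sd)$error_rate
  }, numeric(1))
  expect_gt(mean(accs), 0.70)
  expect_lt(mean(accs), 0.85)
  expect_true(all(accs > 0.65 & accs < 0.90))
})
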