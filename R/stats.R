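# Population statistics on coefficient matrices: constrained ordination
# (CAP on Euclidean distances = redundancy analysis of the coefficients),
# distance-based permutation ANOVA, cluster-plot summaries, and LDA error
# estimation by cross-validation or bootstrap.

# run `expr` under a temporary RNG state seeded with `seed` (NULL = leave
# the RNG alone)
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Canonical analysis of principal coordinates (Euclidean)
#'
#' Constrained ordination of a coefficient matrix by group membership.
#' With Euclidean distances CAP reduces to redundancy analysis: the centred
#' coefficients are projected onto the group-indicator space and the fitted
#' values eigen-decomposed. Implemented via [vegan::capscale()].
#'
#' @param coeffs numeric matrix, fish x coefficients; needs more fish than
#'   coefficients.
#' @param classes group labels, length `nrow(coeffs)`.
#' @return list of class `oto_cap`: `site_scores` (fish x constrained
#'   axes), `eigenvalues`, `eig_ratio` (fraction of constrained variation
#'   per axis), `classes`, and the underlying vegan `ordination`.
#' @export
cap <- function(coeffs, classes) {
  coeffs <- as.matrix(coeffs)
  classes <- factor(classes)
  if (nlevels(droplevels(classes)) < 2L)
    stop("need at least 2 groups for a constrained ordination")
  if (nrow(coeffs) <= ncol(coeffs))
    stop("the number of specimens needs to be larger than the number of ",
         "coefficients (", nrow(coeffs), " <= ", ncol(coeffs), ")")
  dd <- data.frame(grp = droplevels(classes))
  ord <- vegan::capscale(coeffs ~ grp, data = dd, distance = "euclidean")
  eig <- vegan::eigenvals(ord, model = "constrained")
  k <- length(eig)
  sc <- vegan::scores(ord, display = "sites", choices = seq_len(k))
  structure(list(site_scores = as.matrix(sc),
                 eigenvalues = as.numeric(eig),
                 eig_ratio = as.numeric(eig) / sum(eig),
                 classes = dd$grp,
                 ordination = ord),
            class = "oto_cap")
}

#' @export
print.oto_cap <- function(x, ...) {
  k <- length(x$eigenvalues)
  cat("CAP (Euclidean) with", k, "constrained axes\n")
  cat("  eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  cat("  % of among-group variation:",
      paste0(format(100 * x$eig_ratio, digits = 3), "%"), "\n")
  invisible(x)
}

#' Distance-based permutation ANOVA (pseudo-F)
#'
#' Partitions the total sum of squared Euclidean distances of the
#' coefficient matrix into among-group and residual components and tests
#' the pseudo-F ratio by permuting group labels. The p-value uses the
#' add-one convention p = (1 + #permuted F >= observed) / (1 + P), so the
#' smallest attainable p with 1000 permutations is 1/1001 (reported as
#' 0.001 at three decimals).
#'
#' @param coeffs numeric matrix, fish x coefficients.
#' @param classes group labels.
#' @param permutations number of label permutations (default 1000).
#' @param seed optional RNG seed for the permutations.
#' @return list of class `oto_permanova`: `model_df`, `residual_df`,
#'   `model_ss`, `residual_ss`, `model_var`, `residual_var` (inertia,
#'   SS/(n-1) as in constrained-ordination output), `pseudo_F`, `p`,
#'   `permutations`.
#' @export
permutation_anova <- function(coeffs, classes, permutations = 1000L,
                              seed = NULL) {
  coeffs <- as.matrix(coeffs)
  g <- droplevels(factor(classes))
  n <- nrow(coeffs)
  if (length(g) != n) stop("classes must match the coefficient rows")
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (permutations < 1L) stop("permutations must be >= 1")
  X <- sweep(coeffs, 2, colMeans(coeffs))
  ss_tot <- sum(X^2)
  model_ss_for <- function(g) {
    gm <- rowsum(X, g) / as.vector(table(g))
    sum(as.vector(table(g)) * rowSums(gm^2))
  }
  k <- nlevels(g)
  df_m <- k - 1L
  df_r <- n - k
  ss_m <- model_ss_for(g)
  ss_r <- ss_tot - ss_m
  f_obs <- (ss_m / df_m) / (ss_r / df_r)
  f_perm <- .with_seed(seed, {
    vapply(seq_len(permutations), function(i) {
      gp <- sample(g)
      ssm <- model_ss_for(gp)
      (ssm / df_m) / ((ss_tot - ssm) / df_r)
    }, numeric(1))
  })
  p <- (1 + sum(f_perm >= f_obs)) / (1 + permutations)
  structure(list(model_df = df_m, residual_df = df_r,
                 model_ss = ss_m, residual_ss = ss_r,
                 model_var = ss_m / (n - 1), residual_var = ss_r / (n - 1),
                 pseudo_F = f_obs, p = p, permutations = permutations),
            class = "oto_permanova")
}

#' @export
print.oto_permanova <- function(x, ...) {
  tab <- data.frame(Df = c(x$model_df, x$residual_df),
                    Var = round(c(x$model_var, x$residual_var), 4),
                    F = c(round(x$pseudo_F, 4), NA),
                    P = c(round(x$p, 3), NA),
                    row.names = c("Model", "Residual"))
  cat("Permutation ANOVA on Euclidean distances (",
      x$permutations, " permutations)\n", sep = "")
  print(tab)
  invisible(x)
}

#' Group summaries of CAP site scores for a cluster plot
#'
#' Per-group mean site scores on the first (up to) two constrained axes
#' with one-standard-error intervals, plus axis labels carrying the
#' percentage of among-group variation each axis explains.
#'
#' @param cap_result an `oto_cap` object.
#' @param classes optional group labels (default: those stored in the CAP).
#' @return data.frame with one row per group: mean, SE and n per axis;
#'   attribute `axis_labels` holds e.g. `"CAP1 (86.8%)"`.
#' @export
cluster_plot_data <- function(cap_result, classes = NULL) {
  stopifnot(inherits(cap_result, "oto_cap"))
  g <- droplevels(factor(if (is.null(classes)) cap_result$classes else classes))
  sc <- cap_result$site_scores
  naxes <- min(2L, ncol(sc))
  out <- data.frame(group = levels(g),
                    n = as.vector(table(g)))
  for (a in seq_len(naxes)) {
    v <- sc[, a]
    mu <- tapply(v, g, mean)
    se <- tapply(v, g, function(z)
      if (length(z) > 1L) stats::sd(z) / sqrt(length(z)) else 0)
    out[[paste0("mean", a)]] <- as.numeric(mu)
    out[[paste0("se", a)]] <- as.numeric(se)
  }
  labs <- paste0("CAP", seq_len(naxes), " (",
                 round(100 * cap_result$eig_ratio[seq_len(naxes)], 1), "%)")
  attr(out, "axis_labels") <- labs
  out
}

#' Cluster plot of CAP scores
#'
#' Individual fish as small letters, group means as large letters with
#' +/- 1 SE intervals on both axes, as commonly drawn for otolith CAP
#' ordinations.
#'
#' @inheritParams cluster_plot_data
#' @param ... passed to [graphics::plot()].
#' @return the [cluster_plot_data()] table, invisibly.
#' @export
cluster_plot <- function(cap_result, classes = NULL, ...) {
  dat <- cluster_plot_data(cap_result, classes)
  g <- droplevels(factor(if (is.null(classes)) cap_result$classes else classes))
  sc <- cap_result$site_scores
  labs <- attr(dat, "axis_labels")
  y <- if (ncol(sc) > 1L) sc[, 2] else rep(0, nrow(sc))
  graphics::plot(sc[, 1], y, type = "n",
                 xlab = labs[1], ylab = if (length(labs) > 1L) labs[2] else "",
                 las = 1, ...)
  graphics::text(sc[, 1], y, labels = tolower(substr(as.character(g), 1, 1)),
                 col = as.integer(g), cex = 0.6)
  my <- if ("mean2" %in% names(dat)) dat$mean2 else rep(0, nrow(dat))
  sy <- if ("se2" %in% names(dat)) dat$se2 else rep(0, nrow(dat))
  graphics::arrows(dat$mean1 - dat$se1, my, dat$mean1 + dat$se1, my,
                   angle = 90, code = 3, length = 0.04)
  graphics::arrows(dat$mean1, my - sy, dat$mean1, my + sy,
                   angle = 90, code = 3, length = 0.04)
  graphics::text(dat$mean1, my, labels = dat$group, font = 2,
                 col = seq_len(nrow(dat)))
  invisible(dat)
}

#' Linear-discriminant classification error
#'
#' Misclassification rate of an LDA classifier estimated by stratified
#' k-fold cross-validation (leave-one-out when `folds` equals the number of
#' fish) or by out-of-bag bootstrap; `"boot632"` applies the 0.632
#' correction mixing the apparent error with the out-of-bag error.
#'
#' @param coeffs numeric matrix, fish x coefficients.
#' @param classes group labels.
#' @param estimator `"cv"`, `"boot"` or `"boot632"`.
#' @param folds folds for cv (default 10); `folds = nrow(coeffs)` gives
#'   leave-one-out.
#' @param reps bootstrap replicates (default 1000).
#' @param seed optional RNG seed for the resampling.
#' @return list of class `oto_lda_error`: `estimator`, `error_rate`,
#'   `replicates`.
#' @export
lda_error <- function(coeffs, classes, estimator = c("cv", "boot", "boot632"),
                      folds = 10L, reps = 1000L, seed = NULL) {
  estimator <- match.arg(estimator)
  coeffs <- as.matrix(coeffs)
  g <- droplevels(factor(classes))
  n <- nrow(coeffs)
  if (length(g) != n) stop("classes must match the coefficient rows")
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  # columns with (numerically) no variation carry no discriminant
  # information and trip the within-group covariance estimate; drop them
  sds <- apply(coeffs, 2, stats::sd)
  keep <- sds > 1e-8 * max(sds, 1e-300)
  if (!all(keep)) {
    warning(sum(!keep), " near-constant coefficient(s) dropped from the LDA")
    coeffs <- coeffs[, keep, drop = FALSE]
  }
  fit_predict <- function(train, test) {
    fit <- MASS::lda(coeffs[train, , drop = FALSE], grouping = g[train],
                     tol = 1e-9)
    stats::predict(fit, coeffs[test, , drop = FALSE])$class
  }
  res <- .with_seed(seed, {
    if (estimator == "cv") {
      if (folds < 2L || folds > n) stop("folds must be in 2..n")
      if (folds == n) {
        fold <- seq_len(n)  # leave-one-out
      } else {
        if (min(table(g)) < folds)
          stop("every group needs at least ", folds,
               " fish for ", folds, "-fold cv")
        fold <- integer(n)
        for (lv in levels(g)) {
          idx <- which(g == lv)
          fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
        }
      }
      wrong <- 0L
      for (f in unique(fold)) {
        test <- which(fold == f)
        pred <- fit_predict(which(fold != f), test)
        wrong <- wrong + sum(pred != g[test])
      }
      list(error = wrong / n, reps = length(unique(fold)))
    } else {
      errs <- rep(NA_real_, reps)
      for (b in seq_len(reps)) {
        repeat {
          bi <- sample.int(n, n, replace = TRUE)
          if (nlevels(droplevels(g[bi])) == nlevels(g)) break
        }
        oob <- setdiff(seq_len(n), unique(bi))
        if (!length(oob)) next
        pred <- fit_predict(bi, oob)
        errs[b] <- mean(pred != g[oob])
      }
      oob_err <- mean(errs, na.rm = TRUE)
      if (estimator == "boot632") {
        apparent <- mean(fit_predict(seq_len(n), seq_len(n)) != g)
        list(error = 0.368 * apparent + 0.632 * oob_err, reps = reps)
      } else {
        list(error = oob_err, reps = reps)
      }
    }
  })
  structure(list(estimator = estimator, error_rate = res$error,
                 replicates = res$reps),
            class = "oto_lda_error")
}

#' @export
print.oto_lda_error <- function(x, ...) {
  cat("LDA ", x$estimator, " misclassification rate: ",
      round(x$error_rate, 4), " (", x$replicates, " resamples)\n", sep = "")
  invisible(x)
}
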