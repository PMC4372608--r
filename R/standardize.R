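# Allometric length-standardization of shape coefficients.
#
# Otolith shape co-varies with fish size. For each coefficient we first test
# whether its length slope differs among groups (length x group interaction,
# partial F-test); coefficients with a significant interaction cannot be
# adjusted by a common slope and are omitted. The rest are centred at the
# grand mean length using the pooled common slope from the additive model
# coefficient ~ length + group, which removes the length trend exactly while
# preserving group mean differences.

#' Length-standardize a coefficient matrix
#'
#' @param coeffs numeric matrix, fish x coefficients.
#' @param classes group labels (factor or coercible), length `nrow(coeffs)`.
#' @param lengths fish lengths, length `nrow(coeffs)`, positive.
#' @param bonferroni divide the screening level by the number of
#'   coefficients tested (default FALSE).
#' @param alpha interaction screening level before any correction
#'   (default 0.05).
#' @return list of class `oto_std` with `std_matrix` (fish x kept
#'   coefficients), `kept`, `omitted` (named p-values of screened-out
#'   coefficients), `p_interaction` (all), `slopes` (pooled slopes of kept
#'   coefficients), `alpha`, `bonferroni`.
#' @export
standardize_matrix <- function(coeffs, classes, lengths,
                               bonferroni = FALSE, alpha = 0.05) {
  coeffs <- as.matrix(coeffs)
  classes <- factor(classes)
  lengths <- as.numeric(lengths)
  n <- nrow(coeffs)
  if (length(classes) != n || length(lengths) != n)
    stop("classes and lengths must match the coefficient rows")
  if (anyNA(lengths) || any(lengths <= 0))
    stop("fish lengths must be present and positive")
  if (nlevels(classes) < 2L) stop("need at least 2 groups")
  if (any(table(classes) < 3L))
    stop("every group needs at least 3 fish to estimate slopes")
  K <- ncol(coeffs)
  thr <- if (bonferroni) alpha / K else alpha
  p_int <- numeric(K)
  slopes <- rep(NA_real_, K)
  lbar <- mean(lengths)
  for (j in seq_len(K)) {
    y <- coeffs[, j]
    fit_add <- stats::lm(y ~ lengths + classes)
    fit_int <- stats::lm(y ~ lengths * classes)
    an <- stats::anova(fit_add, fit_int)
    p_int[j] <- an[["Pr(>F)"]][2]
    slopes[j] <- stats::coef(fit_add)[["lengths"]]
  }
  names(p_int) <- colnames(coeffs)
  omit <- which(!is.na(p_int) & p_int < thr)
  kept <- setdiff(seq_len(K), omit)
  if (!length(kept))
    stop("all coefficients screened out by the interaction test")
  std <- coeffs[, kept, drop = FALSE] -
    outer(lengths - lbar, slopes[kept])
  rownames(std) <- rownames(coeffs)
  structure(list(std_matrix = std,
                 kept = kept,
                 omitted = p_int[omit],
                 p_interaction = p_int,
                 slopes = slopes[kept],
                 grand_mean_length = lbar,
                 alpha = alpha, bonferroni = bonferroni,
                 threshold = thr),
            class = "oto_std")
}

#' @export
print.oto_std <- function(x, ...) {
  cat("length-standardized coefficients:", length(x$kept), "kept,",
      length(x$omitted), "omitted (interaction P <",
      format(x$threshold, digits = 3),
      if (x$bonferroni) "Bonferroni-adjusted" else "", ")\n")
  if (length(x$omitted)) {
    cat("omitted:\n")
    print(round(x$omitted, 4))
  }
  invisible(x)
}

#' Length-standardize the project's wavelet and Fourier coefficients
#'
#' Applies [standardize_matrix()] to both coefficient matrices over the
#' active records, storing the standardized matrices for
#' [get_std_wavelet()] / [get_std_fourier()]. Coefficients whose length
#' slope differs among the groups in `classes` (interaction P below the
#' screening level) are omitted automatically; with `bonferroni = TRUE` the
#' level is divided by the number of coefficients of each transform.
#'
#' @param store an `otoshape_project` after [enrich_master_list()].
#' @param classes name of the grouping column (e.g. `"pop"`).
#' @param length_column name of the fish-length column (default
#'   `"length_cm"`).
#' @param bonferroni,alpha see [standardize_matrix()].
#' @return the store with standardized matrices and screening info in
#'   `$std`.
#' @export
std_coefs <- function(store, classes, length_column = "length_cm",
                      bonferroni = FALSE, alpha = 0.05) {
  stopifnot(inherits(store, "otoshape_project"))
  ml <- get_masterlist(store)
  if (!length_column %in% names(ml))
    stop("length column '", length_column, "' not found")
  if (!classes %in% names(ml))
    stop("class column '", classes, "' not found")
  for (what in c("wavelet", "fourier")) {
    res <- standardize_matrix(.get_coef(store, what, FALSE, TRUE),
                              ml[[classes]], ml[[length_column]],
                              bonferroni = bonferroni, alpha = alpha)
    store$std[[what]] <- res$std_matrix
    store$std$info[[what]] <- res[setdiff(names(res), "std_matrix")]
  }
  store
}
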