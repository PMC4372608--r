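# End-to-end workflow orchestration: extract -> smooth -> coefficients ->
# enrich -> standardize -> measure -> stats, resumable from a saved project
# archive, with the effective configuration written next to the outputs.

#' Default workflow configuration
#'
#' @param project_path project directory (`Original/` + `Fixed/` + CSV).
#' @param csv_name metadata CSV name.
#' @param out_dir output directory for tables and the project archive.
#' @param threshold binarization threshold.
#' @param smooth_iterations smoothing passes; 0 skips smoothing.
#' @param class_column,length_column grouping / fish-length columns.
#' @param bonferroni Bonferroni-adjust the interaction screen.
#' @param permutations permutation count for the ANOVA.
#' @param method coefficients used for the statistics stage
#'   (`"wavelet"` or `"fourier"`).
#' @param use_std use length-standardized coefficients in the statistics.
#' @param write_overlay write outline QC overlays.
#' @param seed project-level seed for every stochastic step.
#' @return named list of class `oto_config`.
#' @export
workflow_config <- function(project_path, csv_name = "FISH.csv",
                            out_dir = file.path(project_path, "output"),
                            threshold = 0.2, smooth_iterations = 100L,
                            class_column = "pop",
                            length_column = "length_cm",
                            bonferroni = FALSE, permutations = 1000L,
                            method = "wavelet", use_std = TRUE,
                            write_overlay = FALSE, seed = 1L) {
  structure(list(project_path = project_path, csv_name = csv_name,
                 out_dir = out_dir, threshold = threshold,
                 smooth_iterations = as.integer(smooth_iterations),
                 class_column = class_column, length_column = length_column,
                 bonferroni = bonferroni,
                 permutations = as.integer(permutations),
                 method = match.arg(method, c("wavelet", "fourier")),
                 use_std = use_std, write_overlay = write_overlay,
                 seed = as.integer(seed)),
            class = "oto_config")
}

#' Read / write a workflow configuration file
#'
#' Flat key-value YAML mirroring the [workflow_config()] fields; a run
#' writes its effective configuration next to its outputs so it can be
#' reproduced exactly.
#'
#' @param file config file path.
#' @param config an `oto_config`.
#' @return `read_config` an `oto_config`; `write_config` the path,
#'   invisibly.
#' @export
read_config <- function(file) {
  vals <- yaml::read_yaml(file)
  cfg <- do.call(workflow_config, vals)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, file) {
  stopifnot(inherits(config, "oto_config"))
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' Run the full shape-analysis workflow
#'
#' Executes outline extraction, smoothing, coefficient generation, master
#' list enrichment, length standardization, size measurements, and the
#' statistics stage (CAP, permutation ANOVA, LDA cross-validation) in the
#' standard order. The project archive is saved after each stage, and a
#' previously saved archive is resumed — stages whose products already
#' exist are not recomputed, so removing one outline and re-running only
#' reprocesses that fish. Outputs (coefficient CSVs, measurement table,
#' ANOVA table, CAP scores, config) are written under `config$out_dir`.
#'
#' @param config an `oto_config` from [workflow_config()] or a path to a
#'   YAML config file.
#' @return list with the final `store` and the `results` of the statistics
#'   stage, invisibly.
#' @export
run_workflow <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "oto_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  archive <- file.path(config$out_dir, "project.rds")
  t0 <- Sys.time()
  stage <- function(name, expr) {
    ts <- Sys.time()
    res <- expr
    message(sprintf("[%s] %.1fs", name,
                    as.numeric(difftime(Sys.time(), ts, units = "secs"))))
    res
  }
  store <- if (file.exists(archive)) {
    message("resuming from ", archive)
    load_project_archive(archive)
  } else {
    stage("load", load_project(config$project_path, config$csv_name))
  }
  store <- stage("extract",
                 detect_outline(store, threshold = config$threshold,
                                write_overlay = config$write_overlay))
  save_project(store, archive)
  if (config$smooth_iterations > 0L &&
      store$smooth_iterations != config$smooth_iterations) {
    store <- stage("smooth",
                   smooth_outlines(store, config$smooth_iterations))
    save_project(store, archive)
  }
  store <- stage("coefficients", generate_shape_coefficients(store))
  store <- stage("enrich", enrich_master_list(store))
  std_ok <- store$capabilities$standardization &&
    config$class_column %in% names(store$master)
  if (std_ok) {
    store <- stage("standardize",
                   std_coefs(store, classes = config$class_column,
                             length_column = config$length_column,
                             bonferroni = config$bonferroni))
  }
  save_project(store, archive)
  meas <- stage("measure", get_measurements(store))
  utils::write.csv(meas, file.path(config$out_dir, "measurements.csv"),
                   row.names = FALSE)
  for (m in c("wavelet", "fourier")) {
    export_coefficients(store, file.path(config$out_dir,
                                         paste0(m, "_coefficients.csv")),
                        method = m)
    if (std_ok)
      export_coefficients(store,
                          file.path(config$out_dir,
                                    paste0(m, "_coefficients_std.csv")),
                          method = m, std = TRUE)
  }
  results <- NULL
  coeffs <- NULL
  classes <- NULL
  if (config$class_column %in% names(store$master)) {
    coeffs <- if (config$use_std && std_ok)
      .get_coef(store, config$method, TRUE, TRUE)
    else .get_coef(store, config$method, FALSE, TRUE)
    classes <- get_masterlist(store)[[config$class_column]]
    if (nrow(coeffs) <= ncol(coeffs)) {
      warning("statistics stage skipped: the number of specimens (",
              nrow(coeffs), ") needs to be larger than the number of ",
              "coefficients (", ncol(coeffs), ")")
      coeffs <- NULL
    }
  }
  if (!is.null(coeffs)) {
    results <- stage("stats", {
      cap_res <- cap(coeffs, classes)
      an <- permutation_anova(coeffs, classes,
                              permutations = config$permutations,
                              seed = config$seed)
      cl <- cluster_plot_data(cap_res)
      err <- lda_error(coeffs, classes, estimator = "cv",
                       seed = config$seed)
      utils::write.csv(
        data.frame(key = rownames(coeffs), pop = classes,
                   cap_res$site_scores),
        file.path(config$out_dir, "cap_scores.csv"), row.names = FALSE)
      utils::write.csv(
        data.frame(term = c("Model", "Residual"),
                   Df = c(an$model_df, an$residual_df),
                   Var = c(an$model_var, an$residual_var),
                   F = c(an$pseudo_F, NA), P = c(an$p, NA)),
        file.path(config$out_dir, "permutation_anova.csv"),
        row.names = FALSE)
      list(cap = cap_res, anova = an, cluster = cl, lda_cv = err)
    })
  }
  write_config(config, file.path(config$out_dir, "config.yml"))
  save_project(store, archive)
  message(sprintf("workflow finished in %.1fs",
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(store = store, results = results))
}
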