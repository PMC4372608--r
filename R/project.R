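# Project container: metadata CSV + Original/ + Fixed/ image trees, traced
# outlines, coefficient matrices and the active-record filter. The container
# is a plain S3 list so it serializes cleanly.

oto_key <- function(folder, picname) paste(folder, picname, sep = "/")

#' Load an otolith shape-analysis project
#'
#' The project directory must contain `Original/` and `Fixed/` image trees
#' (area subfolders holding JPEGs) and a metadata CSV with one row per fish.
#' Columns `folder` and `picname` are mandatory and identify each image as
#' `Fixed/<folder>/<picname>.jpg`; `length_cm` enables allometric
#' standardization and `cal` (pixels per mm) enables calibrated
#' measurements. Any further columns (population labels, dates, ...) are
#' passed through verbatim. Comma and semicolon separators are
#' auto-detected.
#'
#' @param project_path directory containing `Original/`, `Fixed/` and the CSV.
#' @param csv_name CSV file name within `project_path` (default `FISH.csv`).
#' @return an `otoshape_project` object.
#' @export
load_project <- function(project_path, csv_name = "FISH.csv") {
  if (!dir.exists(project_path)) stop("project path not found: ", project_path)
  for (sub in c("Original", "Fixed")) {
    if (!dir.exists(file.path(project_path, sub)))
      stop("project is missing the '", sub, "' folder")
  }
  csv_path <- file.path(project_path, csv_name)
  if (!file.exists(csv_path)) stop("metadata file not found: ", csv_path)
  header <- readLines(csv_path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr(";", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) ";" else ","
  dat <- utils::read.table(csv_path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           dec = if (sep == ";") "," else ".")
  for (col in c("folder", "picname")) {
    if (!col %in% names(dat))
      stop("mandatory column '", col, "' is missing from ", csv_name)
  }
  dat$folder <- as.character(dat$folder)
  dat$picname <- as.character(dat$picname)
  keys <- oto_key(dat$folder, dat$picname)
  if (anyDuplicated(keys))
    stop("duplicate (folder, picname) pairs in ", csv_name, ": ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  capabilities <- list(
    standardization = "length_cm" %in% names(dat),
    calibration = "cal" %in% names(dat))
  if (!capabilities$standardization)
    warning("no 'length_cm' column: allometric standardization disabled")
  if (!capabilities$calibration)
    warning("no 'cal' column: measurements will be in pixel units")
  if (capabilities$calibration && any(!is.na(dat$cal) & dat$cal <= 0))
    stop("column 'cal' must be positive (pixels per mm)")
  if (capabilities$standardization &&
      any(!is.na(dat$length_cm) & dat$length_cm <= 0))
    stop("column 'length_cm' must be positive")
  structure(list(
    project_path = normalizePath(project_path),
    csv_name = csv_name,
    data = dat,
    outlines = list(),        # key -> traced outline (raster px)
    outlines_smoothed = list(),
    smooth_iterations = 0L,
    threshold_used = NA_real_,
    coef = list(wavelet = NULL, fourier = NULL),
    std = list(wavelet = NULL, fourier = NULL, info = list()),
    master = NULL,
    filter = NULL,
    capabilities = capabilities,
    version = 1L
  ), class = "otoshape_project")
}

#' @export
print.otoshape_project <- function(x, ...) {
  cat("otoshape project:", x$project_path, "\n")
  cat("  records:      ", nrow(x$data), "\n")
  cat("  outlines:     ", length(x$outlines),
      if (x$smooth_iterations > 0L)
        paste0("(smoothed, ", x$smooth_iterations, " iterations)") else "",
      "\n")
  cat("  coefficients: ",
      if (is.null(x$coef$wavelet)) "none" else
        paste0(nrow(x$coef$wavelet), " x ", ncol(x$coef$wavelet), " wavelet, ",
               nrow(x$coef$fourier), " x ", ncol(x$coef$fourier), " Fourier"),
      "\n")
  if (!is.null(x$master))
    cat("  master list:  ", nrow(x$master), "rows,",
        sum(x$filter), "active\n")
  invisible(x)
}

#' @export
summary.otoshape_project <- function(object, ...) {
  print(object)
  if (!is.null(object$master)) {
    cat("\nactive records per folder:\n")
    print(table(get_masterlist(object)$folder))
  }
  invisible(object)
}

#' Join metadata records to coefficient rows
#'
#' Builds the master list: the metadata rows whose (folder, picname) key has
#' an outline and coefficient row, in coefficient-matrix order. Outlines
#' whose key has no CSV row are reported as orphans (warning). Resets the
#' active-record filter to all-TRUE.
#'
#' @param store an `otoshape_project`.
#' @return the store with `$master` and `$filter` set.
#' @export
enrich_master_list <- function(store) {
  stopifnot(inherits(store, "otoshape_project"))
  if (is.null(store$coef$wavelet) || nrow(store$coef$wavelet) == 0L)
    stop("no coefficients present; run generate_shape_coefficients() first")
  keys_coef <- rownames(store$coef$wavelet)
  keys_data <- oto_key(store$data$folder, store$data$picname)
  orphan <- setdiff(keys_coef, keys_data)
  if (length(orphan))
    warning("outlines without metadata rows (orphans): ",
            paste(orphan, collapse = ", "))
  matched <- intersect(keys_coef, keys_data)
  if (!length(matched))
    stop("no (folder, picname) keys match between outlines and metadata; ",
         "check the 'folder' and 'picname' columns")
  message(length(matched), " records matched to coefficients; ",
          length(keys_data) - length(matched), " metadata rows unmatched")
  master <- store$data[match(matched, keys_data), , drop = FALSE]
  rownames(master) <- matched
  store$master <- master
  store$filter <- rep(TRUE, nrow(master))
  store
}

#' Set the active-record filter
#'
#' Downstream getters, standardization, measurements and statistics honor
#' the mask; `use_filter = FALSE` on the getters retrieves the full view.
#'
#' @param store an `otoshape_project` with a master list.
#' @param mask logical vector, one entry per master-list row.
#' @return the store with the filter applied.
#' @export
set_filter <- function(store, mask) {
  stopifnot(inherits(store, "otoshape_project"))
  if (is.null(store$master)) stop("run enrich_master_list() before filtering")
  mask <- as.logical(mask)
  if (length(mask) != nrow(store$master) || anyNA(mask))
    stop("filter mask must be logical of length ", nrow(store$master))
  store$filter <- mask
  store
}

#' Retrieve the master list
#'
#' @param store an `otoshape_project` with a master list.
#' @param use_filter honor the active-record filter (default TRUE).
#' @return data.frame of metadata rows aligned with the coefficient matrices.
#' @export
get_masterlist <- function(store, use_filter = TRUE) {
  stopifnot(inherits(store, "otoshape_project"))
  if (is.null(store$master)) stop("run enrich_master_list() first")
  if (use_filter) store$master[store$filter, , drop = FALSE] else store$master
}

.get_coef <- function(store, what, std, use_filter) {
  m <- if (std) store$std[[what]] else store$coef[[what]]
  if (is.null(m))
    stop("no ", if (std) "standardized " else "", what,
         " coefficients present")
  if (is.null(store$master)) {
    if (use_filter) stop("run enrich_master_list() before filtered access")
    return(m)
  }
  keys <- rownames(get_masterlist(store, use_filter))
  if (!length(keys)) stop("no active records (filter selects 0 rows)")
  missing <- setdiff(keys, rownames(m))
  if (length(missing))
    stop("no coefficient rows for active records: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) " ...")
  m[keys, , drop = FALSE]
}

#' Coefficient matrix getters
#'
#' Rows are fish (aligned with [get_masterlist()]), columns are shape
#' coefficients (`W1..W64` wavelet, `F1..F45` Fourier). The standardized
#' getters return the length-adjusted matrices from [std_coefs()], which may
#' have fewer columns (interaction-screened coefficients are omitted).
#'
#' @param store an `otoshape_project`.
#' @param use_filter honor the active-record filter (default TRUE).
#' @return numeric matrix.
#' @export
get_wavelet <- function(store, use_filter = TRUE)
  .get_coef(store, "wavelet", FALSE, use_filter)

#' @rdname get_wavelet
#' @export
get_fourier <- function(store, use_filter = TRUE)
  .get_coef(store, "fourier", FALSE, use_filter)

#' @rdname get_wavelet
#' @export
get_std_wavelet <- function(store, use_filter = TRUE)
  .get_coef(store, "wavelet", TRUE, use_filter)

#' @rdname get_wavelet
#' @export
get_std_fourier <- function(store, use_filter = TRUE)
  .get_coef(store, "fourier", TRUE, use_filter)

#' Save / reload a project archive
#'
#' Serializes the whole project container (metadata, outlines, coefficient
#' matrices, filter state) to a single versioned archive file, and restores
#' it bit-for-bit.
#'
#' @param store an `otoshape_project`.
#' @param file archive path.
#' @return `save_project` the path invisibly; `load_project_archive` the
#'   restored `otoshape_project`.
#' @export
save_project <- function(store, file) {
  stopifnot(inherits(store, "otoshape_project"))
  saveRDS(store, file)
  invisible(file)
}

#' @rdname save_project
#' @export
load_project_archive <- function(file) {
  store <- readRDS(file)
  if (!inherits(store, "otoshape_project") || is.null(store$version))
    stop("not an otoshape project archive: ", file)
  store
}

#' Export a coefficient matrix as CSV
#'
#' Writes key columns `folder,picname` followed by the coefficient columns.
#'
#' @param store an `otoshape_project` (after [enrich_master_list()]).
#' @param file output CSV path.
#' @param method `"wavelet"` or `"fourier"`.
#' @param std export the length-standardized matrix?
#' @param use_filter honor the active-record filter.
#' @return the path, invisibly.
#' @export
export_coefficients <- function(store, file, method = c("wavelet", "fourier"),
                                std = FALSE, use_filter = TRUE) {
  method <- match.arg(method)
  m <- .get_coef(store, method, std, use_filter)
  ml <- get_masterlist(store, use_filter)
  out <- cbind(ml[, c("folder", "picname")], as.data.frame(m))
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}
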