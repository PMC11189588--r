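#' Read and write ROI time series
#'
#' Series are stored as delimited text (rows = ROIs, columns = samples,
#' first column the ROI label) with a YAML sidecar carrying the sampling
#' rate, segment boundaries and identifiers. `path` is the base name: data
#' go to `<path>.tsv`, metadata to `<path>.yaml`.
#'
#' @param ts a [roi_series()].
#' @param path base path (without extension).
#' @return `write_roi_series()` returns `path` invisibly;
#'   `read_roi_series()` returns a [roi_series()].
#' @export
write_roi_series <- function(ts, path) {
  stopifnot(inherits(ts, "roi_series"))
  df <- data.frame(roi = ts$roi_labels, ts$data, check.names = FALSE)
  write.table(df, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  meta <- list(fs = ts$fs, roi_labels = as.list(ts$roi_labels),
               segment_bounds = apply(ts$segment_bounds, 1, as.list),
               subject_id = ts$subject_id, group = ts$group)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_roi_series
#' @export
read_roi_series <- function(path) {
  raw <- read.table(paste0(path, ".tsv"), sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  raw[[1]] <- as.character(raw[[1]])
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  data <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(data) <- "double"
  sb <- do.call(rbind, lapply(meta$segment_bounds, function(s)
    c(start = s$start, end = s$end)))
  roi_series(data, fs = meta$fs, roi_labels = raw[[1]],
             segment_bounds = sb,
             subject_id = meta$subject_id %||% NA_character_,
             group = meta$group %||% NA_character_)
}

#' Write / read a labelled matrix with a metadata header
#'
#' Serializes ATMs and connectivity matrices as TSV with ROI labels as
#' header row and first column, preceded by `#`-prefixed metadata comment
#' lines (kind, threshold, bin, delta, avalanche count, band and the like).
#'
#' @param x a `transition_matrix` or `connectivity_matrix`.
#' @param path output file path.
#' @return `write_matrix_tsv()` returns `path` invisibly;
#'   `read_matrix_tsv()` returns the object rebuilt from the file.
#' @export
write_matrix_tsv <- function(x, path) {
  if (inherits(x, "transition_matrix")) {
    mat <- x$probs
    meta <- c(kind = "atm", delta_bins = x$delta_bins,
              n_avalanches = x$n_avalanches_averaged,
              normalization = x$normalization)
  } else if (inherits(x, "connectivity_matrix")) {
    mat <- x$values
    meta <- c(kind = x$kind, band_lo = x$band[1], band_hi = x$band[2])
  } else abort("`x` must be a transition_matrix or connectivity_matrix.")
  labs <- rownames(mat) %||% paste0("roi_", seq_len(nrow(mat)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), meta), con)
  writeLines(paste(c("roi", labs), collapse = "\t"), con)
  for (i in seq_len(nrow(mat)))
    writeLines(paste(c(labs[i], format(mat[i, ], digits = 10, trim = TRUE)),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), ":\\s*")[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  body <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                     sep = "\t", check.names = FALSE)
  mat <- as.matrix(body[, -1, drop = FALSE])
  rownames(mat) <- body[[1]]
  if (identical(meta$kind, "atm")) {
    structure(list(probs = mat, delta_bins = as.integer(meta$delta_bins),
                   n_avalanches_averaged = as.integer(meta$n_avalanches),
                   ancestor_counts = NULL, roi_labels = body[[1]],
                   normalization = meta$normalization),
              class = "transition_matrix")
  } else {
    structure(list(values = mat,
                   band = c(as.numeric(meta$band_lo), as.numeric(meta$band_hi)),
                   kind = meta$kind, roi_labels = body[[1]]),
              class = "connectivity_matrix")
  }
}

#' Write / read a subject manifest
#'
#' The manifest is a TSV with columns `subject_id`, `group` and (optionally)
#' `path`, the base path of the subject's series files.
#'
#' @param manifest a data frame with at least `subject_id` and `group`.
#' @param path file path.
#' @return `read_manifest()` returns a tibble.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  as_tibble(read.table(path, sep = "\t", header = TRUE,
                       colClasses = "character"))
}

#' Write a cohort to disk
#'
#' Writes every subject's series (TSV + YAML sidecar), a manifest TSV and
#' the ground-truth propagation graphs of the two groups.
#'
#' @param cohort a `cohort` from [make_cohort()].
#' @param dir output directory (created if missing).
#' @return The manifest tibble (with `path` column) invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    base <- file.path(dir, cohort$subjects[[i]]$subject_id)
    write_roi_series(cohort$subjects[[i]], base)
    paths[i] <- base
  }
  manifest <- dplyr::mutate(cohort$manifest, path = paths)
  write_manifest(manifest, file.path(dir, "manifest.tsv"))
  for (g in names(cohort$models)) {
    gm <- cohort$models[[g]]$graph
    df <- data.frame(roi = paste0("roi_", seq_len(nrow(gm))), gm)
    write.table(df, file.path(dir, sprintf("truth_graph_%s.tsv", g)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(manifest)
}

#' Serialize a classification report to JSON
#'
#' Per-split records (metrics, hyperparameters, confusion counts, ROC curve
#' points), the summary block and the configuration, suitable for archival
#' and downstream plotting.
#'
#' @param report a `classification_report`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "classification_report"))
  per_split <- report$per_split
  roc <- lapply(per_split$roc_curve, function(cv)
    list(fpr = cv$fpr, tpr = cv$tpr))
  per_split$roc_curve <- NULL
  out <- list(
    per_split = per_split, roc_curves = roc,
    summary = report$summary,
    config = unclass(report$config),
    positive_class = report$positive_class,
    feature_kind = report$feature_kind
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write an importance map as TSV
#'
#' Edge importances keyed by `"roiA->roiB"` (ATM) or `"roiA--roiB"` (ImCoh),
#' followed by a second file with node importances if `node_path` is given.
#'
#' @param imp an `importance_map`.
#' @param path edge TSV path.
#' @param node_path optional node TSV path.
#' @return `path` invisibly.
#' @export
write_importance_tsv <- function(imp, path, node_path = NULL) {
  stopifnot(inherits(imp, "importance_map"))
  write.table(imp$edge, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(node_path))
    write.table(imp$node, node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
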