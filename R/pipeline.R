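#' Pipeline configuration
#'
#' Resolves every knob of the end-to-end workflow: the analysis band, the
#' feature kind, avalanche parameters, spectral parameters, the classifier
#' configuration and the output directory. Named bands: `"broadband"`
#' (3-40 Hz), `"narrowband"` (3-14 Hz), or a numeric `c(lo, hi)`; `NULL`
#' disables band filtering.
#'
#' @param band `"broadband"`, `"narrowband"`, numeric `c(lo, hi)` in Hz, or
#'   `NULL` for no filtering of the ROI series before feature extraction.
#' @param feature_kind `"atm"` or `"imcoh"`.
#' @param threshold_z,bin_size,min_duration_bins,delta_bins avalanche
#'   parameters (used when `feature_kind = "atm"`).
#' @param spectral a [spectral_params()] (used when
#'   `feature_kind = "imcoh"`); its band is set from `band` when one is
#'   given.
#' @param classifier a [classifier_config()].
#' @param truncate_s optional uniform duration (seconds) to which every
#'   recording is truncated before feature extraction.
#' @param filter_order Butterworth order for [filter_band()].
#' @param out_dir output directory for artifacts, or `NULL` to skip writing.
#' @param seed seed recorded in the report (the classifier seed governs the
#'   splits).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(band = NULL, feature_kind = c("atm", "imcoh"),
                            threshold_z = 2, bin_size = 1L,
                            min_duration_bins = 2L, delta_bins = 1L,
                            spectral = spectral_params(),
                            classifier = classifier_config(),
                            truncate_s = NULL, filter_order = 4,
                            out_dir = NULL, seed = 42L) {
  feature_kind <- match.arg(feature_kind)
  if (is.character(band))
    band <- switch(band, broadband = c(3, 40), narrowband = c(3, 14),
                   abort("unknown named band; use 'broadband', 'narrowband' or c(lo, hi)."))
  if (!is.null(band)) spectral$band <- band
  structure(
    list(band = band, feature_kind = feature_kind, threshold_z = threshold_z,
         bin_size = as.integer(bin_size),
         min_duration_bins = as.integer(min_duration_bins),
         delta_bins = as.integer(delta_bins), spectral = spectral,
         classifier = classifier, truncate_s = truncate_s,
         filter_order = filter_order, out_dir = out_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the end-to-end classification pipeline
#'
#' From a cohort (in memory, or a manifest of series files on disk) to a
#' classification report and importance map: optional truncation to a
#' uniform duration, optional zero-phase band-pass filtering, feature
#' extraction (ATM or ImCoh edges), repeated shuffle-split SVM
#' classification, and coefficient-based importance. When
#' `config$out_dir` is set, the report (JSON), the per-subject feature
#' matrices (TSV), the importance map (TSV) and the resolved configuration
#' (YAML, with a hash for reproducibility checks) are written there.
#'
#' @param input a `cohort`, a list of labelled [roi_series()], or the path of
#'   a manifest TSV (columns `subject_id`, `group`, `path`).
#' @param config a [pipeline_config()].
#' @return A list: `report` ([fit_predict_splits()] output), `importance`
#'   ([importance()] output), `features` (the `feature_set`), `config`.
#' @export
run_pipeline <- function(input, config = pipeline_config()) {
  subjects <- load_pipeline_input(input)
  groups <- vapply(subjects, function(s) s$group, character(1))
  if (length(unique(groups)) != 2 || min(table(groups)) < 4)
    abort("manifest must list two groups with at least 4 subjects each.")
  fs <- unique(vapply(subjects, function(s) s$fs, numeric(1)))
  if (length(fs) != 1) abort("all subjects must share the sampling rate.")
  labs <- lapply(subjects, function(s) s$roi_labels)
  if (!all(vapply(labs, identical, logical(1), labs[[1]])))
    abort("all subjects must share ROI labels and order.")
  if (!is.null(config$truncate_s)) {
    subjects <- lapply(subjects, truncate_series, duration_s = config$truncate_s)
    inform(sprintf("recordings truncated to %.1f s.", config$truncate_s))
  }
  if (!is.null(config$band))
    subjects <- lapply(subjects, filter_band, band = config$band,
                       order = config$filter_order)
  features <- if (config$feature_kind == "atm") {
    cohort_atm_features(subjects, threshold_z = config$threshold_z,
                        bin_size = config$bin_size,
                        min_duration_bins = config$min_duration_bins,
                        delta_bins = config$delta_bins)
  } else {
    cohort_imcoh_features(subjects, params = config$spectral)
  }
  report <- fit_predict_splits(features, config$classifier)
  imp <- tryCatch(importance(features, config$classifier),
                  error = function(e) { warn(conditionMessage(e)); NULL })
  if (!is.null(config$out_dir)) write_pipeline_artifacts(
    config$out_dir, report, imp, features, config)
  list(report = report, importance = imp, features = features, config = config)
}

load_pipeline_input <- function(input) {
  if (inherits(input, "cohort")) return(input$subjects)
  if (is.character(input) && length(input) == 1) {
    manifest <- read_manifest(input)
    if (!all(c("subject_id", "group", "path") %in% names(manifest)))
      abort("manifest must have columns subject_id, group, path.")
    root <- dirname(input)
    return(lapply(seq_len(nrow(manifest)), function(i) {
      p <- manifest$path[i]
      if (!file.exists(paste0(p, ".tsv"))) p <- file.path(root, basename(p))
      if (!file.exists(paste0(p, ".tsv")))
        abort(sprintf("unreadable series for subject %s: %s",
                      manifest$subject_id[i], manifest$path[i]))
      ts <- read_roi_series(p)
      ts$subject_id <- manifest$subject_id[i]
      ts$group <- manifest$group[i]
      ts
    }))
  }
  if (is.list(input)) return(input)
  abort("`input` must be a cohort, a list of roi_series, or a manifest path.")
}

write_pipeline_artifacts <- function(dir, report, imp, features, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_report_json(report, file.path(dir, "report.json"))
  if (!is.null(imp))
    write_importance_tsv(imp, file.path(dir, "importance_edges.tsv"),
                         file.path(dir, "importance_nodes.tsv"))
  feat <- data.frame(subject_id = rownames(features$matrix),
                     group = as.character(features$labels),
                     features$matrix, check.names = FALSE)
  write.table(feat, file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  resolved <- resolve_config_yaml(config)
  writeLines(c(sprintf("# config hash: %s", config_hash(resolved)),
               sprintf("# written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
               resolved),
             file.path(dir, "config.yaml"))
  invisible(dir)
}

resolve_config_yaml <- function(config) {
  cl <- unclass(config)
  cl$spectral <- unclass(cl$spectral)
  cl$classifier <- unclass(cl$classifier)
  strsplit(yaml::as.yaml(cl), "\n")[[1]]
}

# order-stable polynomial rolling hash of the resolved configuration text
config_hash <- function(lines) {
  bytes <- utf8ToInt(paste(lines, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
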