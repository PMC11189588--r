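#' ROI time-series container
#'
#' Bundles a real-valued `n_rois x n_samples` matrix of source-level activity
#' with its sampling rate, region labels, and the boundaries of contiguous
#' recording segments. Segments mark discontinuities left by upstream epoch
#' removal: avalanche detection and spectral windows never cross them.
#'
#' All sample/bin intervals in this package are 0-based and half-open
#' (`[start, end)`), while ROI indices follow R's 1-based convention.
#'
#' @param data numeric matrix, rows = ROIs, columns = samples.
#' @param fs sampling rate in Hz.
#' @param roi_labels character vector of region names; defaults to
#'   `rownames(data)` or `"roi_1"...`.
#' @param segment_bounds integer matrix with columns `start`, `end` (0-based,
#'   half-open, in samples). Default: one segment covering the recording.
#' @param subject_id,group optional identifiers carried through the pipeline.
#' @return An object of class `roi_series`.
#' @examples
#' x <- roi_series(matrix(rnorm(200), 2), fs = 100)
#' x
#' @export
roi_series <- function(data, fs, roi_labels = NULL, segment_bounds = NULL,
                       subject_id = NA_character_, group = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data)) abort("`data` must be a numeric matrix.")
  if (nrow(data) < 2) abort("`data` must have at least 2 ROIs (rows).")
  if (!all(is.finite(data))) abort("`data` contains non-finite values.")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) abort("`fs` must be a positive scalar.")
  n <- nrow(data); m <- ncol(data)
  if (is.null(roi_labels)) roi_labels <- rownames(data) %||% paste0("roi_", seq_len(n))
  if (length(roi_labels) != n) abort("`roi_labels` length must equal nrow(data).")
  if (anyDuplicated(roi_labels)) abort("`roi_labels` must be unique.")
  if (is.null(segment_bounds)) segment_bounds <- cbind(start = 0L, end = m)
  segment_bounds <- validate_segments(segment_bounds, m, min_len = 2L)
  rownames(data) <- roi_labels
  structure(
    list(data = data, fs = fs, roi_labels = roi_labels,
         segment_bounds = segment_bounds,
         subject_id = subject_id, group = group),
    class = "roi_series"
  )
}

# segments: 0-based half-open, ordered, non-overlapping, jointly covering
validate_segments <- function(sb, n_total, min_len = 1L) {
  sb <- as.matrix(sb)
  if (ncol(sb) != 2) abort("`segment_bounds` needs two columns (start, end).")
  storage.mode(sb) <- "integer"
  colnames(sb) <- c("start", "end")
  if (any(sb[, "end"] - sb[, "start"] < min_len))
    abort(sprintf("every segment must span at least %d samples.", min_len))
  o <- order(sb[, "start"])
  sb <- sb[o, , drop = FALSE]
  if (sb[1, "start"] != 0L || sb[nrow(sb), "end"] != n_total ||
      (nrow(sb) > 1 && any(sb[-1, "start"] != sb[-nrow(sb), "end"])))
    abort("segments must be non-overlapping, ordered and jointly cover all samples.")
  sb
}

#' @export
print.roi_series <- function(x, ...) {
  cat(sprintf("<roi_series> %d ROIs x %d samples @ %g Hz (%.1f s, %d segment%s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$segment_bounds), if (nrow(x$segment_bounds) == 1) "" else "s"))
  if (!is.na(x$subject_id)) cat("  subject:", x$subject_id,
                                if (!is.na(x$group)) paste0(" group: ", x$group), "\n")
  invisible(x)
}

#' @export
dim.roi_series <- function(x) dim(x$data)

#' Slice a time window out of a recording
#'
#' Extracts samples `[start, start + n)` (0-based) as a new single-segment
#' `roi_series`. The window must lie within one recording segment.
#'
#' @param ts a [roi_series()].
#' @param start 0-based first sample.
#' @param n number of samples.
#' @return A `roi_series` covering the window.
#' @export
slice_series <- function(ts, start, n) {
  stopifnot(inherits(ts, "roi_series"))
  if (!segment_contains(ts$segment_bounds, start, start + n))
    abort("requested window crosses a segment boundary or the recording edge.")
  roi_series(ts$data[, (start + 1):(start + n), drop = FALSE], fs = ts$fs,
             roi_labels = ts$roi_labels, subject_id = ts$subject_id, group = ts$group)
}

segment_contains <- function(sb, start, end) {
  any(sb[, "start"] <= start & sb[, "end"] >= end)
}

#' Zero-phase band-pass filter of ROI series
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass of the given
#' order to every ROI, independently within every recording segment so the
#' filter never runs across a discontinuity.
#'
#' @param ts a [roi_series()].
#' @param band numeric `c(f_lo, f_hi)` in Hz, inside `(0, fs/2)`.
#' @param order Butterworth order (applied twice by filtfilt). Default 4.
#' @return A filtered `roi_series`.
#' @export
filter_band <- function(ts, band, order = 4) {
  stopifnot(inherits(ts, "roi_series"), length(band) == 2)
  if (band[1] <= 0 || band[2] >= ts$fs / 2 || band[1] >= band[2])
    abort("`band` must satisfy 0 < f_lo < f_hi < fs/2.")
  bf <- signal::butter(order, band / (ts$fs / 2), type = "pass")
  out <- ts$data
  for (s in seq_len(nrow(ts$segment_bounds))) {
    idx <- (ts$segment_bounds[s, "start"] + 1):ts$segment_bounds[s, "end"]
    out[, idx] <- t(apply(ts$data[, idx, drop = FALSE], 1,
                          function(row) signal::filtfilt(bf, row)))
  }
  roi_series(out, fs = ts$fs, roi_labels = ts$roi_labels,
             segment_bounds = ts$segment_bounds,
             subject_id = ts$subject_id, group = ts$group)
}

#' Truncate a recording to a uniform duration
#'
#' Keeps the first `duration_s` seconds (whole segments, then a partial final
#' segment if needed). Used to equalise recording lengths across subjects
#' before feature extraction.
#'
#' @param ts a [roi_series()].
#' @param duration_s target duration in seconds.
#' @return A truncated `roi_series`.
#' @export
truncate_series <- function(ts, duration_s) {
  stopifnot(inherits(ts, "roi_series"))
  n_keep <- floor(duration_s * ts$fs)
  if (n_keep > ncol(ts$data)) abort(sprintf(
    "subject %s: recording (%.1f s) shorter than requested duration (%.1f s).",
    ts$subject_id, ncol(ts$data) / ts$fs, duration_s))
  sb <- ts$segment_bounds
  sb <- sb[sb[, "start"] < n_keep, , drop = FALSE]
  sb[nrow(sb), "end"] <- min(sb[nrow(sb), "end"], n_keep)
  roi_series(ts$data[, seq_len(sb[nrow(sb), "end"]), drop = FALSE], fs = ts$fs,
             roi_labels = ts$roi_labels, segment_bounds = sb,
             subject_id = ts$subject_id, group = ts$group)
}
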