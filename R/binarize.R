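#' Binarize ROI time series by z-score excursions
#'
#' Each ROI is z-scored over the full concatenated recording; a sample is
#' marked active when its absolute z-score exceeds `threshold_z` (both
#' positive and negative excursions count). The result is a
#' `binary_raster` at `bin_size = 1` (one bin per sample).
#'
#' @param ts a [roi_series()].
#' @param threshold_z positive z-score threshold.
#' @return A `binary_raster`: logical `n_rois x n_bins` matrix plus the
#'   threshold, bin size, sampling rate and segment bounds.
#' @examples
#' ts <- roi_series(matrix(rnorm(400), 4), fs = 100)
#' r <- binarize(ts, 2.5)
#' mean(r$bits)
#' @export
binarize <- function(ts, threshold_z) {
  stopifnot(inherits(ts, "roi_series"))
  if (!is.numeric(threshold_z) || length(threshold_z) != 1 || threshold_z <= 0)
    abort("`threshold_z` must be a positive scalar.")
  mu <- rowMeans(ts$data)
  sdv <- apply(ts$data, 1, sd)
  if (any(sdv == 0))
    abort(paste0("zero-variance ROI row(s): ",
                 paste(ts$roi_labels[sdv == 0], collapse = ", ")))
  z <- (ts$data - mu) / sdv
  new_binary_raster(abs(z) > threshold_z, threshold_z = threshold_z,
                    bin_size = 1L, fs = ts$fs,
                    segment_bounds = ts$segment_bounds,
                    roi_labels = ts$roi_labels,
                    subject_id = ts$subject_id, group = ts$group)
}

new_binary_raster <- function(bits, threshold_z, bin_size, fs, segment_bounds,
                              roi_labels, subject_id = NA_character_,
                              group = NA_character_) {
  storage.mode(bits) <- "logical"
  rownames(bits) <- roi_labels
  structure(
    list(bits = bits, threshold_z = threshold_z, bin_size = as.integer(bin_size),
         fs = fs, segment_bounds = segment_bounds, roi_labels = roi_labels,
         subject_id = subject_id, group = group),
    class = "binary_raster"
  )
}

#' @export
print.binary_raster <- function(x, ...) {
  cat(sprintf("<binary_raster> %d ROIs x %d bins (bin %.1f ms, |z| > %g, %.2f%% active)\n",
              nrow(x$bits), ncol(x$bits), 1000 * x$bin_size / x$fs,
              x$threshold_z, 100 * mean(x$bits)))
  invisible(x)
}

#' Coarsen a raster to wider time bins
#'
#' Collapses consecutive non-overlapping groups of `bin_size` sample-level
#' bins into one bin, independently within each recording segment. A ROI is
#' active in the coarse bin when it was active in at least one constituent
#' sample (logical OR). A trailing partial group within a segment is dropped.
#'
#' @param raster a `binary_raster` at `bin_size = 1` (from [binarize()]).
#' @param bin_size integer number of samples per bin (>= 1).
#' @return A `binary_raster` with the new bin size; segment bounds are
#'   re-expressed in coarse-bin indices.
#' @export
rebin <- function(raster, bin_size) {
  stopifnot(inherits(raster, "binary_raster"))
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size < 1) abort("`bin_size` must be an integer >= 1.")
  if (raster$bin_size != 1L) abort("`rebin()` expects a bin_size-1 raster.")
  if (bin_size == 1L) return(raster)
  sb <- raster$segment_bounds
  pieces <- vector("list", nrow(sb))
  new_sb <- matrix(0L, nrow(sb), 2, dimnames = list(NULL, c("start", "end")))
  at <- 0L
  for (s in seq_len(nrow(sb))) {
    len <- sb[s, "end"] - sb[s, "start"]
    nb <- len %/% bin_size
    if (nb > 0) {
      seg <- raster$bits[, (sb[s, "start"] + 1):(sb[s, "start"] + nb * bin_size),
                         drop = FALSE]
      grp <- rep(seq_len(nb), each = bin_size)
      # OR-aggregate: any active sample within the group
      agg <- t(rowsum(t(seg) * 1L, grp, reorder = FALSE)) > 0
      pieces[[s]] <- agg
    } else {
      pieces[[s]] <- raster$bits[, 0, drop = FALSE]
    }
    new_sb[s, ] <- c(at, at + nb)
    at <- at + nb
  }
  keep <- new_sb[, "end"] - new_sb[, "start"] > 0
  bits <- do.call(cbind, pieces)
  new_binary_raster(bits, threshold_z = raster$threshold_z, bin_size = bin_size,
                    fs = raster$fs,
                    segment_bounds = new_sb[keep, , drop = FALSE],
                    roi_labels = raster$roi_labels,
                    subject_id = raster$subject_id, group = raster$group)
}

# slice [start_bin, start_bin + n) out of a raster as a single-segment raster
slice_raster <- function(raster, start_bin, n) {
  if (!segment_contains(raster$segment_bounds, start_bin, start_bin + n))
    abort("requested bin window crosses a segment boundary.")
  new_binary_raster(raster$bits[, (start_bin + 1):(start_bin + n), drop = FALSE],
                    threshold_z = raster$threshold_z, bin_size = raster$bin_size,
                    fs = raster$fs, segment_bounds = cbind(start = 0L, end = n),
                    roi_labels = raster$roi_labels,
                    subject_id = raster$subject_id, group = raster$group)
}
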