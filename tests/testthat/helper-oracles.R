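# Independent oracles and small fixture builders used across the suite.

# wrap a logical matrix as a bin-size-1 raster (optionally with segments)
raster_from_bits <- function(bits, fs = 250, segment_bounds = NULL,
                             threshold_z = 2) {
  bits <- as.matrix(bits) > 0
  rownames(bits) <- paste0("roi_", seq_len(nrow(bits)))
  if (is.null(segment_bounds))
    segment_bounds <- cbind(start = 0L, end = ncol(bits))
  avalanchr:::new_binary_raster(
    bits, threshold_z = threshold_z, bin_size = 1L, fs = fs,
    segment_bounds = segment_bounds, roi_labels = rownames(bits))
}

# brute-force avalanche scanner: enumerate every maximal run of nonzero
# columns inside each segment, then apply edge/duration filters
brute_force_avalanches <- function(bits, segment_bounds, min_duration) {
  out <- list()
  for (s in seq_len(nrow(segment_bounds))) {
    lo <- segment_bounds[s, "start"] + 1L; hi <- segment_bounds[s, "end"]
    t <- lo
    while (t <= hi) {
      if (any(bits[, t])) {
        u <- t
        while (u < hi && any(bits[, u + 1])) u <- u + 1L
        touches_edge <- (t == lo) || (u == hi)
        if (!touches_edge && (u - t + 1L) >= min_duration) {
          out[[length(out) + 1]] <- list(
            start_bin = unname(t - 1L), end_bin = unname(u),
            counts = colSums(bits[, t:u, drop = FALSE]))
        }
        t <- u + 1L
      } else t <- t + 1L
    }
  }
  out
}

# direct product-form branching ratio (no telescoping)
sigma_product_form <- function(counts) {
  N <- length(counts)
  prod((counts[-1] / counts[-N])^(1 / (N - 1)))
}

# naive per-avalanche ATM averaged element-wise, written independently
naive_atm <- function(list_of_bits, n_rois, delta = 1L) {
  acc <- matrix(0, n_rois, n_rois)
  for (B in list_of_bits) {
    N <- ncol(B)
    m <- matrix(0, n_rois, n_rois)
    for (i in seq_len(n_rois)) {
      den <- 0; num <- numeric(n_rois)
      for (t in seq_len(N - delta)) {
        if (B[i, t]) {
          den <- den + 1
          num <- num + B[, t + delta]
        }
      }
      if (den > 0) m[i, ] <- num / den
    }
    acc <- acc + m
  }
  acc / length(list_of_bits)
}

# avalanche object straight from per-bin active sets (bypasses detection)
avalanche_from_sets <- function(sets, start_bin = 0L) {
  avalanchr:::new_avalanche(start_bin, start_bin + length(sets), sets)
}

# small labelled cohort of raw series from two propagation models
tiny_cohort <- function(n_per_group = 5, n_rois = 10, n_bins = 4000,
                        effect_size = 0.5, seed = 7, fs = 250,
                        noise_sd = NULL, burst_z = 2.5) {
  spec <- cohort_spec(n_per_group = n_per_group, n_rois = n_rois,
                      duration_s = n_bins / fs, fs = fs,
                      effect_size = effect_size, noise_sd = noise_sd,
                      burst_amplitude_z = burst_z, seed = seed)
  make_cohort(spec)
}

expect_tibble_names <- function(x, nms) {
  expect_s3_class(x, "tbl_df")
  expect_true(all(nms %in% names(x)))
}
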