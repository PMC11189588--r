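#' Classification accuracy as a function of signal length
#'
#' Quantifies how much recording is needed for the ATM features to support
#' classification. For each requested length, windows are placed uniformly at
#' random (`n_placements` independent draws per subject) within the
#' full-recording binarized raster; ATMs are computed from each window alone,
#' the shuffle-split classification runs, and for every split the median
#' accuracy over placements is recorded. Longer windows average more
#' avalanches, so the per-split accuracy is expected to be non-decreasing in
#' length on effect-bearing cohorts.
#'
#' Binarization (z-scoring) uses the full recording, as in the main
#' pipeline; windows slice the binarized raster and must fit inside a single
#' recording segment. Avalanche parameters are held fixed across lengths.
#'
#' @param cohort a `cohort` or list of labelled [roi_series()].
#' @param lengths_s window lengths in seconds (default
#'   `c(5, 15, 30, 60, 120, 180, 300)`).
#' @param n_placements random placements per length (default 100).
#' @param threshold_z,bin_size,min_duration_bins,delta_bins avalanche
#'   parameters, fixed across lengths.
#' @param cfg a [classifier_config()]; the same seed gives identical split
#'   partitions across lengths and placements.
#' @param placement_seed seed for the window draws (default `cfg$seed + 1`).
#' @return A `window_analysis`: `results` tibble (`length_s`, `split`,
#'   `accuracy` = median over placements), `placement_accuracy` tibble
#'   (`length_s`, `placement`, `split`, `accuracy`), and the settings.
#' @export
window_accuracy <- function(cohort,
                            lengths_s = c(5, 15, 30, 60, 120, 180, 300),
                            n_placements = 100,
                            threshold_z = 2, bin_size = 1L,
                            min_duration_bins = 2L, delta_bins = 1L,
                            cfg = classifier_config(),
                            placement_seed = NULL) {
  subjects <- if (inherits(cohort, "cohort")) cohort$subjects else cohort
  placement_seed <- placement_seed %||% (cfg$seed + 1L)
  labels <- vapply(subjects, function(s) s$group, character(1))
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  rasters <- lapply(subjects, function(s) rebin(binarize(s, threshold_z), bin_size))
  fs_bin <- rasters[[1]]$fs / bin_size  # bins per second
  for (L in lengths_s) {
    need <- as.integer(round(L * fs_bin))
    for (k in seq_along(rasters)) {
      seg_len <- rasters[[k]]$segment_bounds[, "end"] - rasters[[k]]$segment_bounds[, "start"]
      if (!any(seg_len >= need)) abort(sprintf(
        "subject %s: no recording segment holds a %.0f s window.", ids[k], L))
    }
  }
  rows <- list(); placed <- list()
  with_preserved_seed(placement_seed, {
    for (L in sort(lengths_s)) {
      need <- as.integer(round(L * fs_bin))
      acc <- matrix(NA_real_, cfg$n_splits, n_placements)
      seen <- list()  # placements drawing identical windows reuse the result
      for (p in seq_len(n_placements)) {
        starts <- integer(length(rasters))
        for (k in seq_along(rasters)) {
          sb <- rasters[[k]]$segment_bounds
          ok <- which(sb[, "end"] - sb[, "start"] >= need)
          weights <- sb[ok, "end"] - sb[ok, "start"] - need + 1L
          seg <- if (length(ok) == 1) ok else sample(ok, 1, prob = weights)
          starts[k] <- sb[seg, "start"] +
            sample.int(weights[match(seg, ok)], 1) - 1L
        }
        key <- paste(starts, collapse = ",")
        if (!is.null(seen[[key]])) {
          acc[, p] <- seen[[key]]
          next
        }
        atms <- vector("list", length(rasters))
        for (k in seq_along(rasters)) {
          win <- slice_raster(rasters[[k]], starts[k], need)
          avs <- detect_avalanches(win, min_duration_bins)
          avs <- avs[vapply(avs, function(a) a$n_bins >= delta_bins + 1L, logical(1))]
          if (length(avs) == 0) abort(sprintf(
            "subject %s: window of %.0f s contains no avalanche; use longer windows or a lower threshold.",
            ids[k], L))
          atms[[k]] <- compute_atm(avs, n_rois = nrow(win$bits),
                                   delta_bins = delta_bins,
                                   roi_labels = win$roi_labels)
        }
        feats <- vectorize(atms, labels = labels, subject_ids = ids)
        rep <- fit_predict_splits(feats, cfg)
        acc[, p] <- rep$per_split$accuracy
        seen[[key]] <- acc[, p]
      }
      rows[[length(rows) + 1]] <- tibble(
        length_s = L, split = seq_len(cfg$n_splits),
        accuracy = apply(acc, 1, median))
      placed[[length(placed) + 1]] <- tibble(
        length_s = L,
        placement = rep(seq_len(n_placements), each = cfg$n_splits),
        split = rep(seq_len(cfg$n_splits), times = n_placements),
        accuracy = as.vector(acc))
    }
  })
  structure(
    list(results = dplyr::bind_rows(rows),
         placement_accuracy = dplyr::bind_rows(placed),
         lengths_s = sort(lengths_s), n_placements = n_placements,
         config = cfg, threshold_z = threshold_z, bin_size = bin_size,
         min_duration_bins = min_duration_bins, delta_bins = delta_bins,
         placement_seed = placement_seed),
    class = "window_analysis"
  )
}

#' @export
print.window_analysis <- function(x, ...) {
  cat(sprintf("<window_analysis> lengths %s s, %d placements, %d splits\n",
              paste(x$lengths_s, collapse = "/"), x$n_placements,
              x$config$n_splits))
  s <- dplyr::summarise(dplyr::group_by(x$results, .data$length_s),
                        mean_accuracy = mean(.data$accuracy), .groups = "drop")
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %5.0f s  mean accuracy %.3f\n", s$length_s[i], s$mean_accuracy[i]))
  invisible(x)
}

#' @describeIn window_accuracy per-length, per-split accuracies as a tibble.
#' @param x a `window_analysis`.
#' @param ... unused.
#' @method tidy window_analysis
#' @export
tidy.window_analysis <- function(x, ...) x$results

#' @describeIn window_accuracy mean accuracy per window length with split SD.
#' @method glance window_analysis
#' @export
glance.window_analysis <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(x$results, .data$length_s),
                   mean_accuracy = mean(.data$accuracy),
                   sd_accuracy = sd(.data$accuracy), .groups = "drop")
}

#' @describeIn window_accuracy accuracy distribution per window length.
#' @param object a `window_analysis`.
#' @method autoplot window_analysis
#' @export
autoplot.window_analysis <- function(object, ...) {
  ggplot(object$results,
         aes(x = factor(.data$length_s), y = .data$accuracy)) +
    geom_violin(fill = "salmon", alpha = 0.5, scale = "width") +
    geom_jitter(width = 0.1, alpha = 0.4, size = 0.8) +
    labs(x = "signal length (s)", y = "accuracy (median over placements)",
         title = "Classification accuracy vs signal length") +
    theme_minimal()
}
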