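#' Avalanche transition matrix (ATM)
#'
#' Entry (i, j) estimates the probability that ROI j is active `delta_bins`
#' after ROI i, conditional on i being active, within an avalanche. Per
#' avalanche the conditional is the ratio of co-activation counts to
#' ancestor-bin counts; per-avalanche matrices are then averaged element-wise
#' across avalanches. Rows of ROIs that never served as ancestor are zero
#' (the feature space stays dense and fixed). With `normalization =
#' "binary"` the per-avalanche matrix is instead the 0/1 indicator that the
#' (i, j) succession occurred at least once in that avalanche.
#'
#' @param avs list of `avalanche` objects (see [detect_avalanches()]).
#' @param n_rois total number of ROIs (fixes the matrix dimension).
#' @param delta_bins succession lag in bins; default 1 (about 4 ms for 4 ms
#'   bins).
#' @param roi_labels optional ROI names for the dimnames.
#' @param normalization `"conditional"` (default) or `"binary"`, see above.
#' @return A `transition_matrix` with fields `probs` (n x n, entries in
#'   \[0,1\]), `delta_bins`, `n_avalanches_averaged` and `ancestor_counts`
#'   (per ROI, number of (avalanche, bin) pairs where it was an ancestor).
#' @examples
#' ts <- roi_series(matrix(rnorm(4000), 4), fs = 250)
#' avs <- detect_avalanches(binarize(ts, 1.5), 2)
#' atm <- compute_atm(avs, n_rois = 4)
#' atm$probs
#' @export
compute_atm <- function(avs, n_rois, delta_bins = 1L, roi_labels = NULL,
                        normalization = c("conditional", "binary")) {
  normalization <- match.arg(normalization)
  if (length(avs) == 0) abort("empty avalanche list.")
  delta_bins <- as.integer(delta_bins)
  if (delta_bins < 1) abort("`delta_bins` must be >= 1.")
  n_rois <- as.integer(n_rois)
  acc <- matrix(0, n_rois, n_rois)
  anc_tot <- numeric(n_rois)
  n_used <- 0L
  for (av in avs) {
    N <- av$n_bins
    if (N < delta_bins + 1L) abort(sprintf(
      "avalanche of %d bins is shorter than delta_bins + 1 = %d.", N, delta_bins + 1L))
    if (max(unlist(av$active_sets)) > n_rois)
      abort("`n_rois` does not cover all ROI indices present in the avalanches.")
    A <- matrix(0, n_rois, N)
    for (j in seq_len(N)) A[av$active_sets[[j]], j] <- 1
    anc <- A[, seq_len(N - delta_bins), drop = FALSE]
    desc <- A[, (1 + delta_bins):N, drop = FALSE]
    num <- anc %*% t(desc)
    den <- rowSums(anc)
    m <- if (normalization == "conditional") num / pmax(den, 1) else (num > 0) * 1
    m[den == 0, ] <- 0
    acc <- acc + m
    anc_tot <- anc_tot + den
    n_used <- n_used + 1L
  }
  probs <- acc / n_used
  if (!is.null(roi_labels)) dimnames(probs) <- list(roi_labels, roi_labels)
  structure(
    list(probs = probs, delta_bins = delta_bins,
         n_avalanches_averaged = n_used, ancestor_counts = anc_tot,
         roi_labels = roi_labels %||% rownames(probs), normalization = normalization),
    class = "transition_matrix"
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d x %d, delta = %d bin(s), %d avalanches averaged\n",
              nrow(x$probs), ncol(x$probs), x$delta_bins, x$n_avalanches_averaged))
  invisible(x)
}

#' @describeIn compute_atm long-format tibble of ATM entries
#'   (`from`, `to`, `prob`).
#' @param x a `transition_matrix`.
#' @param ... unused.
#' @method tidy transition_matrix
#' @export
tidy.transition_matrix <- function(x, ...) {
  labs <- x$roi_labels %||% paste0("roi_", seq_len(nrow(x$probs)))
  tibble(
    from = rep(labs, times = ncol(x$probs)),
    to = rep(labs, each = nrow(x$probs)),
    prob = as.vector(x$probs)
  )
}

#' @describeIn compute_atm heat-map of transition probabilities.
#' @param object a `transition_matrix`.
#' @method autoplot transition_matrix
#' @export
autoplot.transition_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$to, y = .data$from, fill = .data$prob)) +
    geom_tile() +
    scale_fill_viridis_c(name = "P(to | from)") +
    labs(x = "descendant ROI", y = "ancestor ROI",
         title = "Avalanche transition matrix") +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' End-to-end ATM from a ROI time series
#'
#' Convenience wrapper: [binarize()] at `threshold_z`, [rebin()] to
#' `bin_size`, [detect_avalanches()] with `min_duration_bins`, then
#' [compute_atm()].
#'
#' @inheritParams binarize
#' @inheritParams compute_atm
#' @param bin_size samples per bin.
#' @param min_duration_bins minimal avalanche duration in bins.
#' @return A `transition_matrix`, or an error if no avalanche survives the
#'   filters.
#' @export
atm_from_series <- function(ts, threshold_z = 2, bin_size = 1L,
                            min_duration_bins = 2L, delta_bins = 1L,
                            normalization = c("conditional", "binary")) {
  raster <- rebin(binarize(ts, threshold_z), bin_size)
  avs <- detect_avalanches(raster, min_duration_bins)
  avs <- avs[vapply(avs, function(a) a$n_bins >= delta_bins + 1L, logical(1))]
  if (length(avs) == 0) abort(sprintf(
    "subject %s: no avalanche of duration >= %d bins at threshold %.2f.",
    ts$subject_id, as.integer(min_duration_bins), threshold_z))
  compute_atm(avs, n_rois = nrow(ts$data), delta_bins = delta_bins,
              roi_labels = ts$roi_labels, normalization = match.arg(normalization))
}
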