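#' Detect neuronal avalanches in a binary raster
#'
#' An avalanche is a maximal run of contiguous bins in which at least one ROI
#' is active, bounded by fully silent bins. Runs are found independently
#' within each recording segment (no avalanche spans a discontinuity); runs
#' that touch a segment edge are discarded as incomplete, as are runs shorter
#' than `min_duration_bins`.
#'
#' @param raster a `binary_raster`.
#' @param min_duration_bins minimal avalanche duration in bins (>= 1).
#' @return A list of `avalanche` objects ordered by start bin. Each carries
#'   the 0-based half-open bin interval `start_bin`/`end_bin`, the per-bin
#'   active ROI sets (1-based indices), and per-bin activation counts.
#' @examples
#' ts <- roi_series(matrix(rnorm(2000), 4), fs = 250)
#' avs <- detect_avalanches(binarize(ts, 2), min_duration_bins = 2)
#' length(avs)
#' @export
detect_avalanches <- function(raster, min_duration_bins = 1L) {
  stopifnot(inherits(raster, "binary_raster"))
  min_duration_bins <- as.integer(min_duration_bins)
  if (is.na(min_duration_bins) || min_duration_bins < 1)
    abort("`min_duration_bins` must be an integer >= 1.")
  out <- list()
  active <- colSums(raster$bits) > 0
  for (s in seq_len(nrow(raster$segment_bounds))) {
    s0 <- raster$segment_bounds[s, "start"]; s1 <- raster$segment_bounds[s, "end"]
    if (s1 - s0 < 1) next
    seg <- active[(s0 + 1):s1]
    r <- rle(seg)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      if (starts[k] == 1 || ends[k] == length(seg)) next  # touches segment edge
      if (r$lengths[k] < min_duration_bins) next
      cols <- (s0 + starts[k]):(s0 + ends[k])
      sub <- raster$bits[, cols, drop = FALSE]
      out[[length(out) + 1]] <- new_avalanche(
        start_bin = s0 + starts[k] - 1L, end_bin = s0 + ends[k],
        active_sets = lapply(seq_len(ncol(sub)), function(j) unname(which(sub[, j]))))
    }
  }
  out
}

new_avalanche <- function(start_bin, end_bin, active_sets) {
  structure(
    list(start_bin = as.integer(start_bin), end_bin = as.integer(end_bin),
         active_sets = active_sets,
         events_per_bin = vapply(active_sets, length, integer(1)),
         n_bins = as.integer(end_bin - start_bin)),
    class = "avalanche"
  )
}

#' @export
print.avalanche <- function(x, ...) {
  cat(sprintf("<avalanche> bins [%d, %d) size %d events/bin: %s\n",
              x$start_bin, x$end_bin, sum(x$events_per_bin),
              paste(x$events_per_bin, collapse = " ")))
  invisible(x)
}

#' Branching ratio of a single avalanche
#'
#' The geometrically averaged descendant/ancestor ratio over successive bins,
#' \deqn{\sigma_i = \prod_{j=1}^{N-1} \left(\frac{n_{j+1}}{n_j}\right)^{1/(N-1)},}
#' where \eqn{n_j} is the number of activations in bin \eqn{j} and \eqn{N}
#' the avalanche duration in bins. The product telescopes to
#' \eqn{(n_N / n_1)^{1/(N-1)}}; both forms agree and the closed form is used.
#'
#' @param av an `avalanche` (or a bare integer vector of per-bin counts).
#' @return The branching parameter \eqn{\sigma_i} (positive scalar).
#' @export
branching_ratio_avalanche <- function(av) {
  ne <- if (inherits(av, "avalanche")) av$events_per_bin else as.numeric(av)
  N <- length(ne)
  if (N < 2) abort("avalanche has no descendant bin (duration < 2 bins).")
  if (any(ne < 1)) abort("every avalanche bin must contain >= 1 event.")
  (ne[N] / ne[1])^(1 / (N - 1))
}

#' Cohort branching ratio over a set of avalanches
#'
#' Geometric mean of the per-avalanche branching parameters,
#' \deqn{\sigma = \prod_i \sigma_i^{1/N_{aval}},}
#' over the avalanches of duration >= 2 bins (single-bin avalanches carry no
#' descendant information and are excluded). \eqn{\sigma \approx 1} indicates
#' critical cascade dynamics.
#'
#' @param avs list of `avalanche` objects.
#' @param bin_size bin size (samples) recorded in the result, for bookkeeping.
#' @return A `branching_estimate` with fields `sigma`, `sigma_per_avalanche`,
#'   `n_avalanches`, `bin_size`.
#' @export
branching_ratio <- function(avs, bin_size = NA_integer_) {
  keep <- vapply(avs, function(a) a$n_bins >= 2, logical(1))
  if (!any(keep)) abort("no avalanche with duration >= 2 bins.")
  sig <- vapply(avs[keep], branching_ratio_avalanche, numeric(1))
  structure(
    list(sigma = exp(mean(log(sig))), sigma_per_avalanche = sig,
         n_avalanches = sum(keep), bin_size = as.integer(bin_size)),
    class = "branching_estimate"
  )
}

#' @export
print.branching_estimate <- function(x, ...) {
  cat(sprintf("<branching_estimate> sigma = %.4f over %d avalanches (bin %s)\n",
              x$sigma, x$n_avalanches,
              if (is.na(x$bin_size)) "?" else x$bin_size))
  invisible(x)
}

#' @method glance branching_estimate
#' @export
glance.branching_estimate <- function(x, ...) {
  tibble(sigma = x$sigma, n_avalanches = x$n_avalanches, bin_size = x$bin_size)
}

#' Select the time-bin size whose branching ratio is closest to 1
#'
#' For each candidate bin size the raster is re-binned, avalanches are
#' detected, and the cohort branching ratio is estimated; the candidate whose
#' \eqn{\sigma} is closest to 1 wins (ties broken toward the smaller bin),
#' the usual criterion for capturing critical dynamics without artificial
#' sub- or super-sampling.
#'
#' @param raster a `binary_raster` at bin size 1.
#' @param candidate_bins integer vector of candidate bin sizes.
#' @param min_duration_bins minimal avalanche duration passed to
#'   [detect_avalanches()].
#' @return The selected bin size (integer). Candidates yielding no avalanche
#'   of duration >= 2 are skipped with a warning; if all are skipped, error.
#' @export
select_bin_size <- function(raster, candidate_bins, min_duration_bins = 1L) {
  if (length(candidate_bins) == 0) abort("`candidate_bins` must be non-empty.")
  candidate_bins <- as.integer(candidate_bins)
  sig <- rep(NA_real_, length(candidate_bins))
  for (i in seq_along(candidate_bins)) {
    rb <- rebin(raster, candidate_bins[i])
    avs <- detect_avalanches(rb, min_duration_bins)
    ok <- any(vapply(avs, function(a) a$n_bins >= 2, logical(1)))
    if (!ok) {
      warn(sprintf("bin size %d yielded no usable avalanche; skipped.",
                   candidate_bins[i]))
      next
    }
    sig[i] <- branching_ratio(avs, bin_size = candidate_bins[i])$sigma
  }
  if (all(is.na(sig))) abort("no candidate bin size yielded avalanches.")
  pick_bin_by_sigma(candidate_bins, sig)
}

# tie rule: closest |sigma - 1|, then smaller bin
pick_bin_by_sigma <- function(bins, sig) {
  d <- abs(sig - 1)
  ok <- which(!is.na(d))
  ok <- ok[order(d[ok], bins[ok])]
  bins[ok[1]]
}
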