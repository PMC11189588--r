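#' Multitaper spectral parameters
#'
#' Parameters of the DPSS (Slepian) multitaper cross-spectral estimator used
#' for imaginary coherence: window length, overlap, frequency resolution,
#' time-bandwidth product and the analysis band.
#'
#' With `time_bandwidth` NW, `n_tapers` defaults to `2 NW - 1`, the usual
#' count of well-concentrated Slepian tapers. The native frequency grid of a
#' `window_seconds` window is `1 / window_seconds` Hz; `freq_resolution_hz`
#' is validated against it (no zero padding is applied).
#'
#' @param window_seconds taper window length in seconds (default 10).
#' @param overlap_fraction fractional overlap of consecutive windows in
#'   `[0, 1)` (default 0.5).
#' @param freq_resolution_hz required frequency-grid spacing in Hz
#'   (default 0.1).
#' @param band analysis band `c(f_lo, f_hi)` in Hz (default broadband
#'   3-40 Hz).
#' @param time_bandwidth DPSS time-bandwidth product NW (default 2.5).
#' @param n_tapers number of tapers (default `2 * time_bandwidth - 1`).
#' @return A `spectral_params` list.
#' @export
spectral_params <- function(window_seconds = 10, overlap_fraction = 0.5,
                            freq_resolution_hz = 0.1, band = c(3, 40),
                            time_bandwidth = 2.5, n_tapers = NULL) {
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    abort("`overlap_fraction` must be in [0, 1).")
  if (length(band) != 2 || band[1] >= band[2]) abort("`band` must be c(f_lo, f_hi) with f_lo < f_hi.")
  if (1 / window_seconds > freq_resolution_hz + 1e-12)
    abort("window too short for the requested frequency resolution (native grid is 1/window_seconds).")
  n_tapers <- n_tapers %||% as.integer(2 * time_bandwidth - 1)
  structure(
    list(window_seconds = window_seconds, overlap_fraction = overlap_fraction,
         freq_resolution_hz = freq_resolution_hz, band = band,
         time_bandwidth = time_bandwidth, n_tapers = as.integer(n_tapers),
         taper_family = "dpss"),
    class = "spectral_params"
  )
}

#' Discrete prolate spheroidal sequence (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` at time-bandwidth product
#' `nw` by solving the standard symmetric tridiagonal eigenproblem whose
#' eigenvectors are the Slepian sequences. Columns are unit-norm, ordered by
#' concentration, with the usual sign convention (symmetric tapers have
#' positive mean; antisymmetric tapers start with a positive lobe). Results
#' are cached per `(n, nw, k)` within the session.
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product.
#' @param k number of tapers.
#' @return `n x k` matrix of tapers.
#' @export
dpss_tapers <- function(n, nw, k) {
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  if (!is.null(the[[key]])) return(the[[key]])
  if (k >= n) abort("`k` must be smaller than `n`.")
  W <- nw / n
  i <- 0:(n - 1)
  d <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
  e <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- matrix(0, n, n)
  diag(A) <- d
  A[cbind(1:(n - 1), 2:n)] <- e
  A[cbind(2:n, 1:(n - 1))] <- e
  es <- eigen(A, symmetric = TRUE)
  V <- es$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- V[, j]
    if (j %% 2 == 1) { if (sum(v) < 0) V[, j] <- -v }
    else if (sum((n:1) * v) < 0) V[, j] <- -v
  }
  the[[key]] <- V
  V
}

#' Multitaper cross-spectral density of ROI time series
#'
#' Estimates the cross-spectral matrix S_xy(f) for all ROI pairs (including
#' x = y) by averaging DPSS-tapered periodograms over overlapping windows.
#' Windows are laid out within recording segments only, so no window spans a
#' discontinuity. Frequencies are the native DFT grid of the window,
#' restricted to `freq_range` to bound memory.
#'
#' @param ts a [roi_series()].
#' @param params a [spectral_params()].
#' @param freq_range frequencies to retain, `c(f_min, f_max)` in Hz;
#'   defaults to the params band.
#' @return A `cross_spectra` list: `freq` (Hz), `S` (complex array
#'   `n_rois x n_rois x n_freq`), `n_windows`, `params`.
#' @export
cross_spectra <- function(ts, params = spectral_params(),
                          freq_range = params$band) {
  stopifnot(inherits(ts, "roi_series"))
  n_rois <- nrow(ts$data)
  win_n <- round(params$window_seconds * ts$fs)
  if (win_n < 2) abort("window shorter than 2 samples.")
  step <- max(1L, round(win_n * (1 - params$overlap_fraction)))
  freq_all <- (0:(win_n %/% 2)) * ts$fs / win_n
  sel <- which(freq_all >= freq_range[1] - 1e-9 & freq_all <= freq_range[2] + 1e-9)
  if (length(sel) == 0) abort("no grid frequency inside `freq_range`.")
  V <- dpss_tapers(win_n, params$time_bandwidth, params$n_tapers)
  nf <- length(sel)
  S <- array(0 + 0i, dim = c(n_rois, n_rois, nf))
  n_win <- 0L
  for (s in seq_len(nrow(ts$segment_bounds))) {
    s0 <- ts$segment_bounds[s, "start"]; s1 <- ts$segment_bounds[s, "end"]
    if (s1 - s0 < win_n) next
    starts <- seq(s0, s1 - win_n, by = step)
    for (w0 in starts) {
      x <- ts$data[, (w0 + 1):(w0 + win_n), drop = FALSE]
      x <- x - rowMeans(x)
      # tapered FFTs: X[roi, freq, taper]
      X <- array(0 + 0i, dim = c(n_rois, nf, params$n_tapers))
      for (tp in seq_len(params$n_tapers)) {
        F <- mvfft(t(x) * V[, tp])
        X[, , tp] <- t(F[sel, , drop = FALSE])
      }
      for (f in seq_len(nf)) {
        M <- X[, f, , drop = TRUE]
        if (is.null(dim(M))) M <- matrix(M, ncol = 1)
        S[, , f] <- S[, , f] + M %*% Conj(t(M))
      }
      n_win <- n_win + 1L
    }
  }
  if (n_win == 0) abort("recording shorter than one spectral window.")
  S <- S / (n_win * params$n_tapers * ts$fs)
  structure(
    list(freq = freq_all[sel], S = S, n_windows = n_win, params = params,
         roi_labels = ts$roi_labels, fs = ts$fs),
    class = "cross_spectra"
  )
}

#' @export
print.cross_spectra <- function(x, ...) {
  cat(sprintf("<cross_spectra> %d ROIs, %d frequencies (%.2f-%.2f Hz), %d windows x %d tapers\n",
              dim(x$S)[1], length(x$freq), min(x$freq), max(x$freq),
              x$n_windows, x$params$n_tapers))
  invisible(x)
}

#' Imaginary coherence connectivity
#'
#' Computes, per frequency, \deqn{ImCoh_{xy}(f) = \frac{\mathrm{Im}\,
#' S_{xy}(f)}{\sqrt{S_{xx}(f)\,S_{yy}(f)}}} from a multitaper cross-spectral
#' estimate and averages its absolute value over the grid frequencies inside
#' the band. The imaginary part discards zero-lag (volume-conduction-like)
#' coupling, so instantaneously mixed signals score ~0. Output is symmetric
#' with a zero diagonal; entries lie in \[0, 1\].
#'
#' @param ts a [roi_series()].
#' @param params a [spectral_params()]; `params$band` defines the averaging
#'   band (must lie within `[0, fs/2]`).
#' @param signed if `TRUE`, average the signed ImCoh instead of its absolute
#'   value (sign depends on arbitrary lead/lag orientation; default `FALSE`).
#' @param cs optionally, a precomputed [cross_spectra()] covering the band.
#' @return A `connectivity_matrix`: `values` (n x n symmetric), `band`,
#'   `kind = "imcoh"`.
#' @export
imcoh <- function(ts, params = spectral_params(), signed = FALSE, cs = NULL) {
  if (params$band[1] < 0 || params$band[2] > ts$fs / 2)
    abort("`band` must lie within [0, fs/2].")
  if (is.null(cs)) cs <- cross_spectra(ts, params)
  n <- dim(cs$S)[1]
  acc <- matrix(0, n, n)
  for (f in seq_along(cs$freq)) {
    Sf <- cs$S[, , f]
    auto <- Re(diag(Sf))
    if (any(auto <= 0)) abort(sprintf(
      "zero autospectral density for ROI %s at %.2f Hz.",
      cs$roi_labels[which(auto <= 0)[1]], cs$freq[f]))
    den <- sqrt(outer(auto, auto))
    ic <- Im(Sf) / den
    acc <- acc + if (signed) ic else abs(ic)
  }
  vals <- acc / length(cs$freq)
  if (!signed) vals <- (vals + t(vals)) / 2  # enforce exact symmetry
  diag(vals) <- 0
  dimnames(vals) <- list(cs$roi_labels, cs$roi_labels)
  structure(
    list(values = vals, band = params$band, kind = "imcoh",
         roi_labels = cs$roi_labels, signed = signed, n_windows = cs$n_windows),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s, %d ROIs, band %.1f-%.1f Hz\n",
              x$kind, nrow(x$values), x$band[1], x$band[2]))
  invisible(x)
}

#' @describeIn imcoh long-format tibble of connectivity entries.
#' @param x a `connectivity_matrix`.
#' @param ... unused.
#' @method tidy connectivity_matrix
#' @export
tidy.connectivity_matrix <- function(x, ...) {
  labs <- x$roi_labels %||% paste0("roi_", seq_len(nrow(x$values)))
  ut <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble(roi_a = labs[ut[, 1]], roi_b = labs[ut[, 2]],
         value = x$values[ut])
}

#' Surrogate null threshold for band imaginary coherence
#'
#' Recomputes the band ImCoh on surrogates in which every ROI series is
#' independently circularly shifted (preserving each spectrum, destroying
#' cross-ROI phase relations) and returns a per-pair null quantile. Values of
#' the observed ImCoh below this threshold are compatible with no lagged
#' coupling.
#'
#' @inheritParams imcoh
#' @param n_surrogates number of circularly shifted surrogates (default 200).
#' @param probs quantile of the null distribution (default 0.95).
#' @param seed integer seed for the shift draws.
#' @return Matrix of per-pair null thresholds (same shape as the ImCoh
#'   values).
#' @export
imcoh_null_threshold <- function(ts, params = spectral_params(),
                                 n_surrogates = 200, probs = 0.95, seed = 1) {
  n <- nrow(ts$data); m <- ncol(ts$data)
  vals <- array(NA_real_, dim = c(n, n, n_surrogates))
  shifts <- with_preserved_seed(seed, {
    matrix(sample.int(m - 1, n * n_surrogates, replace = TRUE), n, n_surrogates)
  })
  for (b in seq_len(n_surrogates)) {
    shifted <- ts$data
    for (r in seq_len(n)) {
      k <- shifts[r, b]
      shifted[r, ] <- c(ts$data[r, (k + 1):m], ts$data[r, 1:k])
    }
    sts <- roi_series(shifted, fs = ts$fs, roi_labels = ts$roi_labels)
    vals[, , b] <- imcoh(sts, params)$values
  }
  apply(vals, c(1, 2), quantile, probs = probs)
}

# run code under a seed, restoring the caller's RNG state afterwards
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
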