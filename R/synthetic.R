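#' Random propagation model for avalanche dynamics
#'
#' Builds a random directed graph of per-step activation probabilities
#' `P[i, j]` = probability that an activation of ROI i recruits ROI j one bin
#' later. Nonzero weights are drawn uniform and rescaled so the mean row sum
#' over rows with outgoing edges equals `target_rho`, the expected number of
#' descendants per ancestor: `target_rho = 1` puts the cascade at
#' criticality, below 1 subcritical, above 1 supercritical.
#'
#' @param n_rois number of regions.
#' @param density edge density in (0, 1] over the `n (n-1)` ordered pairs
#'   (default 0.5).
#' @param target_rho expected descendants per ancestor (default 1).
#' @param seed integer seed; the graph is reproducible.
#' @param drive_rate per-ROI seeding probability per bin while the network is
#'   silent (default 0.01; low drive keeps avalanche onsets small, which the
#'   telescoped branching estimator needs to stay unbiased).
#' @param refractory_bins bins during which a just-active ROI cannot
#'   re-activate (default 1).
#' @return A `propagation_model` with fields `graph`, `drive_rate`,
#'   `target_rho`, `refractory_bins`, `n_rois`.
#' @export
make_propagation_model <- function(n_rois, density = 0.5, target_rho = 1,
                                   seed = 1, drive_rate = 0.01,
                                   refractory_bins = 1L) {
  if (density <= 0 || density > 1) abort("`density` must be in (0, 1].")
  if (target_rho <= 0) abort("`target_rho` must be positive.")
  if (drive_rate < 0 || drive_rate > 1) abort("`drive_rate` must be in [0, 1].")
  P <- with_preserved_seed(seed, {
    P <- matrix(0, n_rois, n_rois)
    off <- which(row(P) != col(P))
    idx <- sample(off, round(density * length(off)))
    P[idx] <- runif(length(idx), 0.5, 1.5)
    P
  })
  rs <- rowSums(P)
  P <- P * target_rho / mean(rs[rs > 0])
  if (max(P) > 1) P <- pmin(P, 1)
  structure(
    list(graph = P, drive_rate = drive_rate, target_rho = target_rho,
         refractory_bins = as.integer(refractory_bins), n_rois = as.integer(n_rois)),
    class = "propagation_model"
  )
}

#' @export
print.propagation_model <- function(x, ...) {
  cat(sprintf("<propagation_model> %d ROIs, density %.2f, rho %.2f, drive %.3f, refractory %d\n",
              x$n_rois, mean(x$graph[row(x$graph) != col(x$graph)] > 0),
              x$target_rho, x$drive_rate, x$refractory_bins))
  invisible(x)
}

#' Simulate a binary raster from a propagation model
#'
#' Discrete-time stochastic cascade: while the network is silent each ROI
#' seeds independently with `drive_rate`; each ROI active at bin t activates
#' ROI j at t + 1 with probability `P[i, j]`, multiple parents combining by
#' noisy-OR; ROIs active within the last `refractory_bins` bins cannot
#' re-activate. Silent bins separate avalanches by construction.
#'
#' @param model a [make_propagation_model()].
#' @param n_bins number of bins to simulate.
#' @param seed integer seed.
#' @param fs nominal sampling rate attached to the raster (default 250 Hz,
#'   i.e. 4 ms bins).
#' @return A `binary_raster` at bin size 1 (threshold field `NA`).
#' @export
simulate_raster <- function(model, n_bins, seed = 1, fs = 250) {
  stopifnot(inherits(model, "propagation_model"))
  n_bins <- as.integer(n_bins)
  if (n_bins < 1) abort("`n_bins` must be >= 1.")
  n <- model$n_rois
  logq <- log1p(-pmin(model$graph, 1 - 1e-12))
  X <- with_preserved_seed(seed, {
    X <- matrix(FALSE, n, n_bins)
    last_active <- rep.int(-1000000L, n)
    state <- logical(n)
    for (t in seq_len(n_bins)) {
      p <- if (!any(state)) rep(model$drive_rate, n)
           else 1 - exp(colSums(logq[state, , drop = FALSE]))
      newstate <- runif(n) < p
      if (model$refractory_bins > 0)
        newstate[last_active >= t - model$refractory_bins] <- FALSE
      X[, t] <- newstate
      last_active[newstate] <- t
      state <- newstate
    }
    X
  })
  new_binary_raster(X, threshold_z = NA_real_, bin_size = 1L, fs = fs,
                    segment_bounds = cbind(start = 0L, end = n_bins),
                    roi_labels = paste0("roi_", seq_len(n)))
}

#' Render a binary raster as a continuous ROI time series
#'
#' Each active bin contributes a boxcar pulse of `bin_size` samples with
#' random sign; silent samples carry Gaussian background noise. When
#' `noise_sd` is `NULL` (default) the background level is solved per ROI so
#' that, after the z-scoring performed by [binarize()], pulse peaks land at
#' `burst_amplitude_z`; because z-scoring fixes the total variance, pulse
#' height and background level cannot be chosen independently - passing an
#' explicit small `noise_sd` instead yields the low-noise regime where pulse
#' peaks z-score near `1/sqrt(q_r)` (`q_r` = ROI activity fraction) and the
#' binarize/detect round trip is essentially exact.
#'
#' @param raster a `binary_raster` (e.g. from [simulate_raster()]).
#' @param fs output sampling rate (default: the raster's).
#' @param bin_size samples per raster bin (default 1).
#' @param burst_amplitude_z target z-height of pulse peaks (default 2.5).
#' @param noise_sd background noise standard deviation in pulse-amplitude
#'   units, or `NULL` to calibrate from `burst_amplitude_z`.
#' @param seed integer seed for signs and noise.
#' @return A [roi_series()].
#' @export
raster_to_timeseries <- function(raster, fs = NULL, bin_size = 1L,
                                 burst_amplitude_z = 2.5, noise_sd = NULL,
                                 seed = 1) {
  stopifnot(inherits(raster, "binary_raster"))
  if (burst_amplitude_z <= 0) abort("`burst_amplitude_z` must be positive.")
  fs <- fs %||% raster$fs
  bin_size <- as.integer(bin_size)
  n <- nrow(raster$bits); nb <- ncol(raster$bits)
  q <- rowMeans(raster$bits)
  if (is.null(noise_sd)) {
    b2 <- burst_amplitude_z^2
    if (any(q * b2 >= 0.98)) {
      warn("activity too dense for the requested burst_amplitude_z; capping noise at a small floor.")
    }
    nz2 <- pmax((1 / b2 - q) / pmax(1 - q, 1e-9), 1e-6)
    noise_r <- sqrt(nz2)
  } else {
    if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
    noise_r <- rep(noise_sd, n)
  }
  with_preserved_seed(seed, {
    out <- matrix(0, n, nb * bin_size)
    for (r in seq_len(n)) {
      x <- rnorm(nb * bin_size, 0, noise_r[r])
      act <- which(raster$bits[r, ])
      if (length(act) > 0) {
        sign_r <- sample(c(-1, 1), length(act), replace = TRUE)
        for (k in seq_len(bin_size)) {
          x[(act - 1) * bin_size + k] <- rep(sign_r, 1)
        }
      }
      out[r, ] <- x
    }
    sb <- raster$segment_bounds
    roi_series(out, fs = fs, roi_labels = raster$roi_labels,
               segment_bounds = cbind(start = sb[, "start"] * bin_size,
                                      end = sb[, "end"] * bin_size),
               subject_id = raster$subject_id, group = raster$group)
  })
}

#' Cohort specification for the synthetic generator
#'
#' Defaults mirror the study conditions the package targets: 68 cortical
#' ROIs sampled at 250 Hz, 300 s (5 min) of artifact-free signal per subject,
#' and two groups of 30 subjects whose avalanche propagation graphs differ in
#' an `effect_size` fraction of edges.
#'
#' @param n_per_group subjects per group (default 30).
#' @param n_rois regions (default 68).
#' @param duration_s recording length in seconds (default 300).
#' @param fs sampling rate in Hz (default 250).
#' @param effect_size fraction of base-graph edges rewired in group B's
#'   graph, in `[0, 1]` (default 0.5).
#' @param burst_amplitude_z target pulse z-height (default 2.5).
#' @param noise_sd background noise level or `NULL` to calibrate (see
#'   [raster_to_timeseries()]).
#' @param density,target_rho,drive_rate,refractory_bins propagation-model
#'   parameters, see [make_propagation_model()].
#' @param seed master seed; every subject's realization derives from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 30, n_rois = 68, duration_s = 300,
                        fs = 250, effect_size = 0.5, burst_amplitude_z = 2.5,
                        noise_sd = NULL, density = 0.5, target_rho = 1,
                        drive_rate = 0.01, refractory_bins = 1L, seed = 1) {
  if (effect_size < 0 || effect_size > 1) abort("`effect_size` must be in [0, 1].")
  structure(
    list(n_per_group = as.integer(n_per_group), n_rois = as.integer(n_rois),
         duration_s = duration_s, fs = fs, effect_size = effect_size,
         burst_amplitude_z = burst_amplitude_z, noise_sd = noise_sd,
         density = density, target_rho = target_rho, drive_rate = drive_rate,
         refractory_bins = as.integer(refractory_bins), seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# rewire a fraction of edges of a base graph, preserving the weight multiset
perturb_model <- function(model, effect_size, seed) {
  P <- model$graph
  off <- which(row(P) != col(P))
  edges <- off[P[off] > 0]
  empty <- off[P[off] == 0]
  k <- round(effect_size * length(edges))
  if (k > 0) {
    with_preserved_seed(seed, {
      move <- sample(edges, k)
      dest <- sample(empty, min(k, length(empty)))
      w <- P[move]
      P[move] <- 0
      P[dest] <- w[seq_along(dest)]
    })
  }
  out <- model
  out$graph <- P
  out
}

#' Generate a synthetic two-group cohort of ROI time series
#'
#' Group A subjects are independent realizations of a base propagation
#' model; group B subjects use a copy in which an `effect_size` fraction of
#' edges has been rewired to previously empty slots (weights preserved, so
#' overall excitability is matched and the group difference lives purely in
#' the propagation structure). Each subject's raster is rendered to a
#' continuous series via [raster_to_timeseries()].
#'
#' @param spec a [cohort_spec()].
#' @return A `cohort`: list with `subjects` (list of [roi_series()]),
#'   `manifest` (tibble: subject_id, group), `models` (ground-truth
#'   propagation models per group) and `spec`.
#' @examples
#' \donttest{
#' co <- make_cohort(cohort_spec(n_per_group = 3, n_rois = 12, duration_s = 20))
#' co$manifest
#' }
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  base <- make_propagation_model(spec$n_rois, spec$density, spec$target_rho,
                                 seed = spec$seed, drive_rate = spec$drive_rate,
                                 refractory_bins = spec$refractory_bins)
  pert <- perturb_model(base, spec$effect_size, seed = spec$seed + 777)
  n_bins <- as.integer(round(spec$duration_s * spec$fs))
  subjects <- vector("list", 2 * spec$n_per_group)
  ids <- character(2 * spec$n_per_group)
  groups <- character(2 * spec$n_per_group)
  for (i in seq_len(2 * spec$n_per_group)) {
    grp <- if (i <= spec$n_per_group) "A" else "B"
    model <- if (grp == "A") base else pert
    sseed <- spec$seed + 1000L + i
    raster <- simulate_raster(model, n_bins, seed = sseed, fs = spec$fs)
    ts <- raster_to_timeseries(raster, fs = spec$fs, bin_size = 1L,
                               burst_amplitude_z = spec$burst_amplitude_z,
                               noise_sd = spec$noise_sd, seed = sseed + 500000L)
    ts$subject_id <- sprintf("sub-%s%02d", grp,
                             if (grp == "A") i else i - spec$n_per_group)
    ts$group <- grp
    subjects[[i]] <- ts
    ids[i] <- ts$subject_id
    groups[i] <- grp
  }
  structure(
    list(subjects = subjects,
         manifest = tibble(subject_id = ids, group = groups),
         models = list(A = base, B = pert), spec = spec),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%s), %d ROIs, %.0f s @ %g Hz, effect size %.2f\n",
              length(x$subjects),
              paste(sprintf("%s: %d", names(table(x$manifest$group)),
                            table(x$manifest$group)), collapse = ", "),
              x$spec$n_rois, x$spec$duration_s, x$spec$fs, x$spec$effect_size))
  invisible(x)
}
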