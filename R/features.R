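#' Vectorize per-subject matrices into an edge-feature set
#'
#' Turns a list of per-subject `transition_matrix` (directed: all
#' `n (n - 1)` off-diagonal ordered pairs) or `connectivity_matrix`
#' (symmetric: the `n (n - 1) / 2` upper-triangle pairs) into a
#' subjects-by-edges feature matrix. Column order is deterministic:
#' column-major over the off-diagonal (ATM) or upper triangle (ImCoh) of the
#' ROI-by-ROI matrix, with edge labels `"a->b"` / `"a--b"`.
#'
#' @param matrices named or unnamed list of per-subject matrices, all sharing
#'   ROI labels and order.
#' @param labels group label per subject (factor or character; two classes).
#' @param subject_ids optional subject identifiers.
#' @return A `feature_set`: `matrix` (n_subjects x n_edges), `edge_index`
#'   tibble (`col`, `from`, `to`, `label`), `labels`, `feature_kind`
#'   (`"atm"` or `"imcoh"`), `roi_labels`.
#' @export
vectorize <- function(matrices, labels, subject_ids = NULL) {
  if (length(matrices) == 0) abort("`matrices` is empty.")
  kinds <- vapply(matrices, function(m)
    if (inherits(m, "transition_matrix")) "atm"
    else if (inherits(m, "connectivity_matrix")) "imcoh"
    else "?", character(1))
  if (length(unique(kinds)) != 1 || kinds[1] == "?")
    abort("`matrices` must all be transition_matrix or all connectivity_matrix.")
  kind <- kinds[1]
  get_mat <- function(m) if (kind == "atm") m$probs else m$values
  labs0 <- matrices[[1]]$roi_labels %||% paste0("roi_", seq_len(nrow(get_mat(matrices[[1]]))))
  for (m in matrices) {
    ml <- m$roi_labels %||% paste0("roi_", seq_len(nrow(get_mat(m))))
    if (!identical(ml, labs0))
      abort("mismatched ROI labels across subjects; cannot align features.")
  }
  n <- length(labs0)
  if (kind == "atm") {
    idx <- which(row(diag(n)) != col(diag(n)))  # column-major off-diagonal
    sep <- "->"
  } else {
    idx <- which(upper.tri(diag(n)))
    sep <- "--"
  }
  ai <- arrayInd(idx, c(n, n))
  edge_index <- tibble(
    col = seq_along(idx),
    from = labs0[ai[, 1]], to = labs0[ai[, 2]],
    label = paste0(labs0[ai[, 1]], sep, labs0[ai[, 2]])
  )
  X <- t(vapply(matrices, function(m) get_mat(m)[idx], numeric(length(idx))))
  colnames(X) <- edge_index$label
  labels <- factor(labels)
  if (nlevels(labels) != 2) abort("`labels` must contain exactly two classes.")
  if (length(labels) != nrow(X)) abort("one label per subject is required.")
  if (anyNA(X)) abort("feature matrix contains missing values.")
  rownames(X) <- subject_ids %||% names(matrices) %||% paste0("sub_", seq_len(nrow(X)))
  structure(
    list(matrix = X, edge_index = edge_index, labels = labels,
         feature_kind = kind, roi_labels = labs0),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d subjects x %d %s edges (%s)\n",
              nrow(x$matrix), ncol(x$matrix), x$feature_kind,
              paste(sprintf("%s: %d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' ATM edge features for a whole cohort
#'
#' Runs [atm_from_series()] on every subject of a cohort and vectorizes the
#' resulting matrices. Subjects for which no avalanche survives the filters
#' raise an error naming the subject (use [optimize_avalanche_params()] to
#' scan parameter grids tolerantly).
#'
#' @param cohort a `cohort` from [make_cohort()], or a list of
#'   [roi_series()] with `group` fields set.
#' @inheritParams atm_from_series
#' @return A `feature_set` of ATM edges.
#' @export
cohort_atm_features <- function(cohort, threshold_z = 2, bin_size = 1L,
                                min_duration_bins = 2L, delta_bins = 1L,
                                normalization = "conditional") {
  subjects <- if (inherits(cohort, "cohort")) cohort$subjects else cohort
  atms <- lapply(subjects, atm_from_series, threshold_z = threshold_z,
                 bin_size = bin_size, min_duration_bins = min_duration_bins,
                 delta_bins = delta_bins, normalization = normalization)
  vectorize(atms,
            labels = vapply(subjects, function(s) s$group, character(1)),
            subject_ids = vapply(subjects, function(s) s$subject_id, character(1)))
}

#' ImCoh edge features for a whole cohort
#'
#' Runs [imcoh()] on every subject and vectorizes the upper-triangle entries.
#'
#' @inheritParams cohort_atm_features
#' @param params a [spectral_params()].
#' @return A `feature_set` of ImCoh edges.
#' @export
cohort_imcoh_features <- function(cohort, params = spectral_params()) {
  subjects <- if (inherits(cohort, "cohort")) cohort$subjects else cohort
  mats <- lapply(subjects, imcoh, params = params)
  vectorize(mats,
            labels = vapply(subjects, function(s) s$group, character(1)),
            subject_ids = vapply(subjects, function(s) s$subject_id, character(1)))
}
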