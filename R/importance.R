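#' Edge and node feature importance from linear SVM coefficients
#'
#' Re-runs the shuffle-split procedure of [fit_predict_splits()] (same seed,
#' hence identical partitions and hyperparameter choices) and derives the
#' importance of every edge as the median over splits of the absolute
#' classification coefficients of the linear-kernel models. Splits in which
#' the grid search selected the radial-basis kernel carry no per-feature
#' coefficients and are excluded (a message reports how many). Node
#' importance is the arithmetic mean of the importances of the edges
#' incident to the region (both directions for directed ATM edges).
#'
#' @param features a `feature_set`.
#' @param cfg a [classifier_config()].
#' @return An `importance_map`: `edge` tibble (`label`, `from`, `to`,
#'   `importance`) and `node` tibble (`roi`, `importance`), plus the number
#'   of splits used.
#' @export
importance <- function(features, cfg = classifier_config()) {
  res <- svm_shuffle_splits(features, cfg, keep_coefs = TRUE)
  used <- !vapply(res$coefs, is.null, logical(1))
  if (!any(used))
    abort("no split selected a linear kernel; restrict `kernel_grid` to 'linear'.")
  if (any(!used))
    inform(sprintf("%d of %d splits selected the radial kernel and were excluded from the importance median.",
                   sum(!used), length(used)))
  W <- do.call(rbind, res$coefs[used])
  edge_imp <- apply(W, 2, median)
  edge <- dplyr::mutate(features$edge_index, importance = edge_imp)
  node <- purrr::map_dfr(features$roi_labels, function(r) {
    inc <- edge$from == r | edge$to == r
    tibble(roi = r, importance = mean(edge$importance[inc]))
  })
  structure(
    list(edge = dplyr::select(edge, "label", "from", "to", "importance"),
         node = node, n_splits_used = sum(used),
         feature_kind = features$feature_kind),
    class = "importance_map"
  )
}

#' @export
print.importance_map <- function(x, ...) {
  cat(sprintf("<importance_map> %d edges, %d nodes (median over %d linear splits)\n",
              nrow(x$edge), nrow(x$node), x$n_splits_used))
  top <- dplyr::arrange(x$edge, dplyr::desc(.data$importance))[1:min(5, nrow(x$edge)), ]
  cat("  top edges:\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %-24s %.4f\n", top$label[i], top$importance[i]))
  invisible(x)
}

#' @describeIn importance edge- or node-level importances as a tibble.
#' @param x an `importance_map`.
#' @param level `"edge"` (default) or `"node"`.
#' @param ... unused.
#' @method tidy importance_map
#' @export
tidy.importance_map <- function(x, level = c("edge", "node"), ...) {
  level <- match.arg(level)
  if (level == "edge") x$edge else x$node
}

#' @describeIn importance histogram of edge importances (narrow
#'   distributions mean diffuse information; heavy right tails mean a few
#'   edges carry the discrimination).
#' @param object an `importance_map`.
#' @method autoplot importance_map
#' @export
autoplot.importance_map <- function(object, ...) {
  ggplot(object$edge, aes(x = .data$importance)) +
    geom_histogram(bins = 40, fill = "salmon", colour = "white") +
    labs(x = "edge importance (median |coefficient|)", y = "count",
         title = "Distribution of edge importances") +
    theme_minimal()
}
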