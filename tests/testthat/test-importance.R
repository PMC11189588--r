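edgewise_features <- function(n_per_group, n_rois, signal_edge = NULL,
                              shift = 3, seed = 1) {
  # build per-subject ATM-like matrices with one optionally informative edge
  set.seed(seed)
  labs <- paste0("r", seq_len(n_rois))
  mats <- list()
  groups <- rep(c("A", "B"), each = n_per_group)
  for (i in seq_len(2 * n_per_group)) {
    m <- matrix(runif(n_rois * n_rois, 0.2, 0.4), n_rois, n_rois)
    diag(m) <- 0
    if (!is.null(signal_edge) && groups[i] == "B")
      m[signal_edge[1], signal_edge[2]] <- m[signal_edge[1], signal_edge[2]] +
        shift * 0.1
    dimnames(m) <- list(labs, labs)
    mats[[i]] <- structure(
      list(probs = m, delta_bins = 1L, n_avalanches_averaged = 1L,
           ancestor_counts = rep(1, n_rois), roi_labels = labs,
           normalization = "conditional"),
      class = "transition_matrix")
  }
  vectorize(mats, labels = groups)
}

test_that("an injected discriminative edge ranks first", {
  fs <- edgewise_features(15, 6, signal_edge = c(2, 5), shift = 4, seed = 2)
  imp <- importance(fs, classifier_config(kernel_grid = "linear",
                                          n_splits = 15, seed = 3))
  top <- imp$edge$label[which.max(imp$edge$importance)]
  expect_equal(top, "r2->r5")
  expect_true(all(imp$edge$importance >= 0))
})

test_that("node importance is exactly the incident-edge mean", {
  fs <- edgewise_features(8, 5, signal_edge = c(1, 3), seed = 4)
  imp <- importance(fs, classifier_config(kernel_grid = "linear",
                                          n_splits = 8, seed = 5))
  for (r in fs$roi_labels) {
    inc <- imp$edge$from == r | imp$edge$to == r
    expect_equal(imp$node$importance[imp$node$roi == r],
                 mean(imp$edge$importance[inc]), tolerance = 1e-15)
  }
  # the hand-computable 2-ROI case: both nodes average the same two edges
  fs2 <- edgewise_features(8, 2, signal_edge = c(1, 2), seed = 6)
  imp2 <- importance(fs2, classifier_config(kernel_grid = "linear",
                                            n_splits = 8, seed = 7))
  expect_equal(imp2$node$importance[1], mean(imp2$edge$importance))
  expect_equal(imp2$node$importance[1], imp2$node$importance[2])
})

test_that("identical feature columns receive identical (flat) importance", {
  # copies of the same column must share the coefficient magnitude exactly,
  # so a feature space of duplicated columns has a flat importance profile
  set.seed(8)
  base_col <- rnorm(24)
  X <- matrix(rep(base_col, 6), ncol = 6)
  colnames(X) <- paste0("f", 1:6)
  fs <- structure(
    list(matrix = X,
         edge_index = tibble::tibble(col = 1:6, from = paste0("r", 1:6),
                                     to = "hub", label = colnames(X)),
         labels = factor(rep(c("A", "B"), each = 12)),
         feature_kind = "atm", roi_labels = c(paste0("r", 1:6), "hub")),
    class = "feature_set")
  imp <- importance(fs, classifier_config(kernel_grid = "linear",
                                          n_splits = 8, seed = 9))
  spread <- diff(range(imp$edge$importance))
  expect_lt(spread, 0.1 * max(mean(imp$edge$importance), 1e-12))
})

test_that("a null cohort produces no dominant edge", {
  fs_null <- edgewise_features(20, 5, signal_edge = NULL, seed = 8)
  cfg <- classifier_config(kernel_grid = "linear", n_splits = 20, seed = 9)
  imp_null <- importance(fs_null, cfg)
  ratio_null <- max(imp_null$edge$importance) / median(imp_null$edge$importance)
  fs_sig <- edgewise_features(20, 5, signal_edge = c(2, 5), shift = 6, seed = 8)
  imp_sig <- importance(fs_sig, cfg)
  ratio_sig <- max(imp_sig$edge$importance) / median(imp_sig$edge$importance)
  expect_gt(ratio_sig, ratio_null)  # the injected edge dominates only with signal
})

test_that("radial-only grids cannot produce coefficient importances", {
  fs <- edgewise_features(8, 4, signal_edge = c(1, 2), seed = 10)
  expect_error(importance(fs, classifier_config(kernel_grid = "radial",
                                                n_splits = 4, seed = 11)),
               "linear")
})

test_that("importance replays the same splits as the report", {
  fs <- edgewise_features(10, 4, signal_edge = c(2, 3), shift = 4, seed = 12)
  cfg <- classifier_config(kernel_grid = "linear", n_splits = 6, seed = 13)
  rep1 <- fit_predict_splits(fs, cfg)
  imp <- importance(fs, cfg)
  rep2 <- fit_predict_splits(fs, cfg)
  expect_identical(rep1$per_split, rep2$per_split)
  expect_equal(imp$n_splits_used, cfg$n_splits)
})
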