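# feature_set built directly from a numeric matrix (classifier-level fixtures)
feature_set_from_matrix <- function(X, labels) {
  n <- 1 + ncol(X)  # pretend ROI count for plumbing; edges not used here
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  structure(
    list(matrix = X,
         edge_index = tibble::tibble(col = seq_len(ncol(X)),
                                     from = paste0("r", seq_len(ncol(X))),
                                     to = "hub",
                                     label = colnames(X)),
         labels = factor(labels), feature_kind = "atm",
         roi_labels = c(paste0("r", seq_len(ncol(X))), "hub")),
    class = "feature_set")
}

gaussian_features <- function(n_per_group, p, shift, seed, sd = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_group * p, 0, sd), n_per_group),
             matrix(rnorm(n_per_group * p, shift, sd), n_per_group))
  feature_set_from_matrix(X, rep(c("ctrl", "case"), each = n_per_group))
}

test_that("linearly separable clusters classify perfectly", {
  fs <- gaussian_features(12, 20, shift = 8, seed = 1)
  rep <- fit_predict_splits(fs, classifier_config(n_splits = 10, seed = 2))
  expect_equal(mean(rep$per_split$accuracy), 1.0)
  expect_equal(mean(rep$per_split$roc_auc), 1.0)
  expect_true(all(rep$per_split$sensitivity == 1))
  expect_true(all(rep$per_split$specificity == 1))
})

test_that("identical-distribution groups hover at chance", {
  fs <- gaussian_features(15, 30, shift = 0, seed = 3)
  rep <- fit_predict_splits(fs, classifier_config(n_splits = 25, seed = 4))
  expect_lt(abs(mean(rep$per_split$accuracy) - 0.5), 0.15)
})

test_that("the same seed reproduces the report exactly", {
  fs <- gaussian_features(8, 10, shift = 1, seed = 5)
  cfg <- classifier_config(n_splits = 6, seed = 11)
  r1 <- fit_predict_splits(fs, cfg)
  r2 <- fit_predict_splits(fs, cfg)
  expect_identical(r1$per_split, r2$per_split)
  expect_identical(r1$summary, r2$summary)
  r3 <- fit_predict_splits(fs, classifier_config(n_splits = 6, seed = 12))
  expect_false(identical(r1$per_split$accuracy, r3$per_split$accuracy))
})

test_that("metrics recompute exactly from stored confusion counts", {
  fs <- gaussian_features(10, 12, shift = 0.6, seed = 6)
  rep <- fit_predict_splits(fs, classifier_config(n_splits = 12, seed = 7))
  ps <- rep$per_split
  expect_equal(ps$accuracy, (ps$tp + ps$tn) / (ps$tp + ps$tn + ps$fp + ps$fn))
  prec <- ifelse(ps$tp + ps$fp == 0, 0, ps$tp / (ps$tp + ps$fp))
  sens <- ifelse(ps$tp + ps$fn == 0, 0, ps$tp / (ps$tp + ps$fn))
  expect_equal(ps$precision, prec)
  expect_equal(ps$sensitivity, sens)
  expect_equal(ps$specificity, ps$tn / (ps$tn + ps$fp))
  f1 <- ifelse(prec + sens == 0, 0, 2 * prec * sens / (prec + sens))
  expect_equal(ps$f1, f1)
  # summary mean/SD recompute from the per-split arrays
  for (m in c("accuracy", "roc_auc", "f1", "precision", "sensitivity", "specificity")) {
    expect_equal(rep$summary$mean[rep$summary$metric == m], mean(ps[[m]]),
                 tolerance = 1e-12)
    expect_equal(rep$summary$sd[rep$summary$metric == m], sd(ps[[m]]),
                 tolerance = 1e-12)
  }
})

test_that("standardization and grid search never touch test subjects", {
  fs <- gaussian_features(10, 12, shift = 0.8, seed = 8)
  cfg <- classifier_config(n_splits = 12, seed = 9)
  base <- fit_predict_splits(fs, cfg)
  # corrupt a single subject's features wildly; splits holding that subject
  # out in TEST must keep their hyperparameter choice (train-only selection)
  fs2 <- fs
  victim <- 1L
  fs2$matrix[victim, ] <- fs2$matrix[victim, ] * 1000 + 500
  mod <- fit_predict_splits(fs2, cfg)
  # recover each split's test membership by replaying the engine's RNG use
  memb <- avalanchr:::with_preserved_seed(cfg$seed, {
    lapply(seq_len(cfg$n_splits), function(s) {
      test_idx <- avalanchr:::draw_split(fs$labels, cfg$test_fraction)
      invisible(avalanchr:::draw_folds(fs$labels[-test_idx], cfg$inner_folds))
      test_idx
    })
  })
  hit <- 0L
  for (s in seq_len(cfg$n_splits)) {
    if (victim %in% memb[[s]]) {
      hit <- hit + 1L
      expect_identical(base$per_split$kernel[s], mod$per_split$kernel[s])
      expect_identical(base$per_split$cost[s], mod$per_split$cost[s])
      expect_identical(base$per_split$cv_accuracy[s], mod$per_split$cv_accuracy[s])
    }
  }
  expect_gt(hit, 0L)
})

test_that("stratified splits keep both classes in train and test", {
  fs <- gaussian_features(5, 6, shift = 0.5, seed = 10)
  rep <- fit_predict_splits(fs, classifier_config(n_splits = 20, seed = 13))
  # every split's confusion table must contain both classes in test
  expect_true(all(rep$per_split$tp + rep$per_split$fn >= 1))
  expect_true(all(rep$per_split$tn + rep$per_split$fp >= 1))
  tiny <- feature_set_from_matrix(matrix(rnorm(6 * 4), 6),
                                  c("A", "A", "A", "B", "B", "B"))
  expect_error(fit_predict_splits(tiny, classifier_config()), "at least 4")
})

test_that("label permutation stays near chance on a balanced cohort", {
  fs <- gaussian_features(20, 25, shift = 1.2, seed = 14)
  set.seed(15)
  fs$labels <- sample(fs$labels)
  rep <- fit_predict_splits(fs, classifier_config(n_splits = 25, seed = 16))
  expect_lt(abs(mean(rep$per_split$accuracy) - 0.5), 0.12)
})
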