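#' SVM classifier configuration
#'
#' Settings for the repeated stratified shuffle-split evaluation: kernel and
#' regularization grids for the inner 5-fold cross-validated grid search,
#' the number of outer re-shuffling iterations, and the test fraction.
#' The C grid spans a logarithmic ladder 1e-2 ... 1e2.
#'
#' @param kernel_grid kernels to search, subset of `c("linear", "radial")`.
#' @param c_grid positive regularization values C.
#' @param inner_folds folds of the inner grid-search CV (default 5).
#' @param n_splits outer shuffle-split iterations (default 50).
#' @param test_fraction held-out fraction per split (default 0.2).
#' @param seed integer seed fixing all pseudo-randomness.
#' @return A `classifier_config`.
#' @export
classifier_config <- function(kernel_grid = c("linear", "radial"),
                              c_grid = 10^seq(-2, 2),
                              inner_folds = 5L, n_splits = 50L,
                              test_fraction = 0.2, seed = 42L) {
  kernel_grid <- match.arg(kernel_grid, c("linear", "radial"), several.ok = TRUE)
  if (any(c_grid <= 0)) abort("`c_grid` must be positive.")
  if (test_fraction <= 0 || test_fraction >= 1) abort("`test_fraction` must be in (0, 1).")
  if (n_splits < 1) abort("`n_splits` must be >= 1.")
  structure(
    list(kernel_grid = kernel_grid, c_grid = c_grid,
         inner_folds = as.integer(inner_folds), n_splits = as.integer(n_splits),
         test_fraction = test_fraction, seed = as.integer(seed)),
    class = "classifier_config"
  )
}

# stratified indices: per class, draw round(frac * n_c) (at least 1) test subjects
draw_split <- function(y, test_fraction) {
  test <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_test <- max(1L, round(test_fraction * length(idx)))
    if (n_test >= length(idx)) abort("class too small for the requested test fraction.")
    test <- c(test, sample(idx, n_test))
  }
  sort(test)
}

# stratified fold assignment for inner CV
draw_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

svm_fit <- function(X, y, kernel, cost, gamma) {
  e1071::svm(X, y, type = "C-classification", kernel = kernel, cost = cost,
             gamma = gamma, scale = FALSE)
}

# decision scores oriented so larger = more like `positive`
svm_scores <- function(model, X, positive) {
  pr <- predict(model, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  lead <- strsplit(colnames(dv)[1], "/")[[1]][1]
  s <- as.numeric(dv[, 1])
  if (lead != positive) s <- -s
  list(class = pr, score = s)
}

# Both kernels depend on the features only through inner products and
# distances, which an orthonormal basis of the split's row span preserves
# exactly; projecting train and test rows onto that span (rank <= number of
# subjects) makes every QP in the grid search run on a matrix of width
# n_subjects instead of n_edges, with bitwise-equivalent geometry. `basis`
# maps reduced coefficients back to edge space.
project_rows <- function(Xtr, Xte) {
  Z <- rbind(Xtr, Xte)
  sv <- svd(Z, nu = 0)
  keep <- sv$d > max(sv$d) * 1e-10
  V <- sv$v[, keep, drop = FALSE]
  list(tr = Xtr %*% V, te = Xte %*% V, basis = V)
}

split_metrics <- function(truth, pred, score, positive) {
  neg <- setdiff(levels(truth), positive)
  tp <- sum(truth == positive & pred == positive)
  tn <- sum(truth == neg & pred == neg)
  fp <- sum(truth == neg & pred == positive)
  fn <- sum(truth == positive & pred == neg)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  sens <- if (tp + fn == 0) 0 else tp / (tp + fn)
  spec <- if (tn + fp == 0) 0 else tn / (tn + fp)
  f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  roc <- pROC::roc(response = truth, predictor = score,
                   levels = c(neg, positive), direction = "<", quiet = TRUE)
  list(accuracy = (tp + tn) / length(truth),
       roc_auc = as.numeric(pROC::auc(roc)),
       f1 = f1, precision = prec, sensitivity = sens, specificity = spec,
       tp = tp, tn = tn, fp = fp, fn = fn,
       roc_curve = tibble(fpr = rev(1 - roc$specificities),
                          tpr = rev(roc$sensitivities)))
}

# the shuffle-split engine shared by fit_predict_splits() and importance()
svm_shuffle_splits <- function(features, cfg, keep_coefs = FALSE) {
  stopifnot(inherits(features, "feature_set"), inherits(cfg, "classifier_config"))
  X <- features$matrix
  y <- features$labels
  if (min(table(y)) < 4) abort("need at least 4 subjects per class.")
  positive <- levels(y)[2]
  grid <- expand.grid(kernel = cfg$kernel_grid, cost = cfg$c_grid,
                      stringsAsFactors = FALSE)
  # deterministic search order for ties: linear before radial, smaller C first
  grid <- grid[order(match(grid$kernel, c("linear", "radial")), grid$cost), ]
  rows <- vector("list", cfg$n_splits)
  coefs <- if (keep_coefs) vector("list", cfg$n_splits) else NULL
  with_preserved_seed(cfg$seed, {
    for (s in seq_len(cfg$n_splits)) {
      repeat {
        test_idx <- draw_split(y, cfg$test_fraction)
        train_idx <- setdiff(seq_along(y), test_idx)
        if (nlevels(droplevels(y[train_idx])) == 2 &&
            nlevels(droplevels(y[test_idx])) == 2) break
        inform(sprintf("split %d: single-class partition re-drawn.", s))
      }
      mu <- colMeans(X[train_idx, , drop = FALSE])
      sdv <- apply(X[train_idx, , drop = FALSE], 2, sd)
      sdv[sdv == 0] <- 1  # degenerate features kept, unit scale
      Xtr <- sweep(sweep(X[train_idx, , drop = FALSE], 2, mu), 2, sdv, "/")
      Xte <- sweep(sweep(X[test_idx, , drop = FALSE], 2, mu), 2, sdv, "/")
      ytr <- y[train_idx]; yte <- y[test_idx]
      gamma <- 1 / ncol(X)  # RBF width on the edge-space scale
      pr <- project_rows(Xtr, Xte)
      fold <- draw_folds(ytr, cfg$inner_folds)
      cv_acc <- vapply(seq_len(nrow(grid)), function(g) {
        acc <- 0; used <- 0L
        for (f in seq_len(cfg$inner_folds)) {
          tr <- fold != f
          if (all(tr)) next  # fold empty (training set smaller than k folds)
          if (nlevels(droplevels(ytr[tr])) < 2) return(NA_real_)
          m <- svm_fit(pr$tr[tr, , drop = FALSE], ytr[tr],
                       grid$kernel[g], grid$cost[g], gamma)
          acc <- acc + mean(predict(m, pr$tr[!tr, , drop = FALSE]) == ytr[!tr])
          used <- used + 1L
        }
        acc / used
      }, numeric(1))
      best <- which.max(cv_acc)  # first max: linear, then smaller C, wins ties
      model <- svm_fit(pr$tr, ytr, grid$kernel[best], grid$cost[best], gamma)
      pred <- svm_scores(model, pr$te, positive)
      met <- split_metrics(yte, pred$class, pred$score, positive)
      rows[[s]] <- tibble(
        split = s, kernel = grid$kernel[best], cost = grid$cost[best],
        cv_accuracy = cv_acc[best],
        accuracy = met$accuracy, roc_auc = met$roc_auc, f1 = met$f1,
        precision = met$precision, sensitivity = met$sensitivity,
        specificity = met$specificity,
        tp = met$tp, tn = met$tn, fp = met$fp, fn = met$fn,
        roc_curve = list(met$roc_curve)
      )
      if (keep_coefs && grid$kernel[best] == "linear") {
        w_r <- as.numeric(crossprod(model$coefs, model$SV))
        coefs[[s]] <- abs(as.numeric(pr$basis %*% w_r))
      }
    }
  })
  list(per_split = dplyr::bind_rows(rows), coefs = coefs, positive = positive)
}

#' Repeated stratified shuffle-split SVM classification
#'
#' Evaluates how well the edge features separate the two groups: for each of
#' `n_splits` stratified 80/20 subject-level partitions, features are
#' standardized with training-set statistics only, kernel and C are chosen by
#' an inner `inner_folds`-fold cross-validated grid search on the training
#' partition, and accuracy, ROC AUC, F1, precision, sensitivity and
#' specificity are computed on the held-out subjects. With a fixed
#' `cfg$seed` the whole procedure is deterministic.
#'
#' @param features a `feature_set` from [vectorize()] /
#'   [cohort_atm_features()] / [cohort_imcoh_features()].
#' @param cfg a [classifier_config()].
#' @return A `classification_report`: `per_split` tibble (metrics, chosen
#'   hyperparameters, confusion counts and a ROC-curve list column),
#'   `summary` tibble (mean and SD per metric), `config`, `positive_class`.
#' @export
fit_predict_splits <- function(features, cfg = classifier_config()) {
  res <- svm_shuffle_splits(features, cfg, keep_coefs = FALSE)
  new_classification_report(res$per_split, cfg, res$positive,
                            feature_kind = features$feature_kind)
}

new_classification_report <- function(per_split, cfg, positive, feature_kind = NA) {
  metrics <- c("accuracy", "roc_auc", "f1", "precision", "sensitivity", "specificity")
  summary <- tidyr::pivot_longer(per_split[, c("split", metrics)],
                                 dplyr::all_of(metrics),
                                 names_to = "metric", values_to = "value")
  summary <- dplyr::summarise(dplyr::group_by(summary, .data$metric),
                              mean = mean(.data$value), sd = sd(.data$value),
                              .groups = "drop")
  summary <- summary[match(metrics, summary$metric), ]
  structure(
    list(per_split = per_split, summary = summary, config = cfg,
         positive_class = positive, feature_kind = feature_kind),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %d splits, positive class '%s'%s\n",
              nrow(x$per_split), x$positive_class,
              if (is.na(x$feature_kind)) "" else paste0(", features: ", x$feature_kind)))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-12s %.3f +/- %.3f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  invisible(x)
}

#' @describeIn fit_predict_splits per-split metrics as a tibble.
#' @param x a `classification_report`.
#' @param ... unused.
#' @method tidy classification_report
#' @export
tidy.classification_report <- function(x, ...) {
  dplyr::select(x$per_split, -"roc_curve")
}

#' @describeIn fit_predict_splits one-row summary (mean and SD per metric).
#' @method glance classification_report
#' @export
glance.classification_report <- function(x, ...) {
  out <- as.list(setNames(x$summary$mean, x$summary$metric))
  names(out) <- paste0("mean_", names(out))
  sds <- as.list(setNames(x$summary$sd, paste0("sd_", x$summary$metric)))
  tibble::as_tibble(c(out, sds, list(n_splits = nrow(x$per_split))))
}

#' @describeIn fit_predict_splits distribution of split accuracies plus the
#'   mean ROC curve.
#' @param object a `classification_report`.
#' @param type `"accuracy"` (default) or `"roc"`.
#' @method autoplot classification_report
#' @export
autoplot.classification_report <- function(object, type = c("accuracy", "roc"), ...) {
  type <- match.arg(type)
  if (type == "accuracy") {
    df <- tidy(object)
    ggplot(df, aes(x = "", y = .data$accuracy)) +
      geom_violin(fill = "salmon", alpha = 0.5) +
      geom_jitter(width = 0.08, alpha = 0.6) +
      labs(x = NULL, y = "accuracy",
           title = "Classification accuracy across shuffle splits") +
      theme_minimal()
  } else {
    curves <- dplyr::bind_rows(object$per_split$roc_curve, .id = "split")
    grid_fpr <- seq(0, 1, by = 0.02)
    mean_tpr <- vapply(grid_fpr, function(f) {
      mean(vapply(object$per_split$roc_curve, function(cv) {
        max(cv$tpr[cv$fpr <= f + 1e-12])
      }, numeric(1)))
    }, numeric(1))
    ggplot(tibble(fpr = grid_fpr, tpr = mean_tpr), aes(.data$fpr, .data$tpr)) +
      geom_line(colour = "salmon", linewidth = 1) +
      ggplot2::geom_abline(linetype = 2, colour = "grey60") +
      labs(x = "false positive rate", y = "true positive rate",
           title = "Mean ROC across splits") +
      theme_minimal()
  }
}
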