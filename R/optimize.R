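#' Grid optimization of avalanche threshold and minimal duration
#'
#' Runs the full ATM + classification pipeline for every combination of
#' z-score threshold and minimal avalanche duration and returns the pair
#' maximizing classification accuracy (ties broken toward the higher
#' threshold, then the shorter duration). Two judgment modes exist:
#' `"nested"` (default) scores a pair by the mean inner-CV accuracy of the
#' chosen models, which does not touch held-out subjects; `"test"` scores by
#' mean held-out accuracy, which is optimistic when the selected pair is
#' subsequently reported as *the* performance - prefer the nested mode for
#' honest use and treat the full grid (returned for audit) as descriptive.
#'
#' @param cohort a `cohort` or list of labelled [roi_series()].
#' @param threshold_grid z-score thresholds to scan (default
#'   `seq(1.2, 3.0, by = 0.3)`).
#' @param min_duration_grid minimal durations in bins (default `2:8`).
#' @param cfg a [classifier_config()].
#' @param bin_size,delta_bins fixed avalanche parameters.
#' @param mode `"nested"` or `"test"`, see above.
#' @return A list: `threshold_z`, `min_duration_bins`, `report` (the
#'   [fit_predict_splits()] report refit at the winning pair), and `grid`
#'   (tibble of all pairs with their scores; skipped pairs carry `NA`).
#' @export
optimize_avalanche_params <- function(cohort,
                                      threshold_grid = seq(1.2, 3.0, by = 0.3),
                                      min_duration_grid = 2:8,
                                      cfg = classifier_config(),
                                      bin_size = 1L, delta_bins = 1L,
                                      mode = c("nested", "test")) {
  mode <- match.arg(mode)
  if (length(threshold_grid) == 0 || length(min_duration_grid) == 0)
    abort("parameter grids must be non-empty.")
  grid <- expand.grid(threshold_z = threshold_grid,
                      min_duration_bins = min_duration_grid)
  grid$score <- NA_real_
  grid$mean_test_accuracy <- NA_real_
  for (i in seq_len(nrow(grid))) {
    feats <- tryCatch(
      cohort_atm_features(cohort, threshold_z = grid$threshold_z[i],
                          bin_size = bin_size,
                          min_duration_bins = grid$min_duration_bins[i],
                          delta_bins = delta_bins),
      error = function(e) {
        inform(sprintf("threshold %.2f, duration %d skipped: %s",
                       grid$threshold_z[i], grid$min_duration_bins[i],
                       conditionMessage(e)))
        NULL
      })
    if (is.null(feats)) next
    rep <- fit_predict_splits(feats, cfg)
    grid$mean_test_accuracy[i] <- mean(rep$per_split$accuracy)
    grid$score[i] <- if (mode == "nested") mean(rep$per_split$cv_accuracy)
                     else grid$mean_test_accuracy[i]
  }
  if (all(is.na(grid$score))) abort("every parameter pair was skipped.")
  # tie rule: best score, then higher threshold, then shorter duration
  ord <- order(-grid$score, -grid$threshold_z, grid$min_duration_bins)
  best <- ord[1]
  feats <- cohort_atm_features(cohort, threshold_z = grid$threshold_z[best],
                               bin_size = bin_size,
                               min_duration_bins = grid$min_duration_bins[best],
                               delta_bins = delta_bins)
  list(threshold_z = grid$threshold_z[best],
       min_duration_bins = grid$min_duration_bins[best],
       report = fit_predict_splits(feats, cfg),
       grid = as_tibble(grid), mode = mode)
}
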