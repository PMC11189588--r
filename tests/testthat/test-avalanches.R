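test_that("a simple raster yields the forced avalanche decomposition", {
  # columns: {}, {1}, {1,2}, {}
  r <- raster_from_bits(rbind(c(0, 1, 1, 0),
                              c(0, 0, 1, 0)))
  avs <- detect_avalanches(r, 1)
  expect_length(avs, 1)
  expect_equal(avs[[1]]$start_bin, 1L)
  expect_equal(avs[[1]]$end_bin, 3L)
  expect_equal(avs[[1]]$events_per_bin, c(1L, 2L))
  expect_equal(avs[[1]]$active_sets, list(1L, c(1L, 2L)))

  expect_length(detect_avalanches(raster_from_bits(matrix(0, 2, 8)), 1), 0)
})

test_that("runs touching a segment edge or too short are discarded", {
  bits <- rbind(c(1, 0, 1, 1, 0, 0, 1, 0, 1),
                c(0, 0, 0, 1, 0, 0, 0, 0, 0))
  r <- raster_from_bits(bits)
  avs <- detect_avalanches(r, 1)
  # run at col 1 touches start; run at col 9 touches end; runs at 3:4 and 7 remain
  expect_equal(vapply(avs, function(a) a$start_bin, integer(1)), c(2L, 6L))
  avs2 <- detect_avalanches(r, 2)
  expect_length(avs2, 1)  # the single-bin run at col 7 is filtered
  expect_equal(avs2[[1]]$n_bins, 2L)

  # a segment boundary splits an apparent run; both halves touch the cut
  r2 <- raster_from_bits(rbind(c(0, 1, 1, 1, 0), c(0, 0, 0, 0, 0)),
                         segment_bounds = cbind(start = c(0L, 3L), end = c(3L, 5L)))
  expect_length(detect_avalanches(r2, 1), 0)
})

test_that("detection agrees with a brute-force maximal-run scanner", {
  set.seed(42)
  for (rep in 1:400) {
    n_rois <- sample(2:6, 1)
    n_bins <- sample(6:12, 1)
    min_dur <- sample(1:3, 1)
    bits <- matrix(rbinom(n_rois * n_bins, 1, runif(1, 0.1, 0.5)),
                   n_rois, n_bins)
    sb <- if (runif(1) < 0.3 && n_bins >= 8)
      cbind(start = c(0L, n_bins %/% 2L), end = c(n_bins %/% 2L, n_bins))
    else cbind(start = 0L, end = n_bins)
    r <- raster_from_bits(bits, segment_bounds = sb)
    got <- detect_avalanches(r, min_dur)
    want <- brute_force_avalanches(r$bits, sb, min_dur)
    expect_equal(length(got), length(want))
    for (k in seq_along(got)) {
      expect_equal(got[[k]]$start_bin, want[[k]]$start_bin)
      expect_equal(got[[k]]$end_bin, want[[k]]$end_bin)
      expect_equal(got[[k]]$events_per_bin, unname(want[[k]]$counts))
    }
  }
})

test_that("per-avalanche branching ratio matches hand calculations", {
  expect_equal(branching_ratio_avalanche(c(1, 2)), 2)
  expect_equal(branching_ratio_avalanche(c(2, 2, 2)), 1)
  expect_equal(branching_ratio_avalanche(c(1, 3, 2)), sqrt(2), tolerance = 1e-12)
  expect_error(branching_ratio_avalanche(c(3)), "descendant")
})

test_that("telescoped closed form equals the bin-by-bin product", {
  set.seed(5)
  for (rep in 1:200) {
    counts <- sample(1:9, sample(2:10, 1), replace = TRUE)
    expect_equal(branching_ratio_avalanche(counts), sigma_product_form(counts),
                 tolerance = 1e-12)
  }
})

test_that("cohort sigma is the geometric mean and excludes single-bin events", {
  a1 <- avalanche_from_sets(list(1L, c(1L, 2L)))        # sigma 2
  a2 <- avalanche_from_sets(list(c(1L, 2L), 1L), 10L)   # sigma 0.5
  single <- avalanche_from_sets(list(1L), 20L)
  est <- branching_ratio(list(a1, a2, single))
  expect_equal(est$sigma, 1)
  expect_equal(est$n_avalanches, 2L)
  expect_equal(branching_ratio(list(a1))$sigma, 2)
  expect_error(branching_ratio(list(single)), ">= 2")
})

test_that("bin selection follows the closest-to-1 rule with smaller-bin ties", {
  expect_equal(avalanchr:::pick_bin_by_sigma(c(1L, 2L), c(1.0, 1.3)), 1L)
  expect_equal(avalanchr:::pick_bin_by_sigma(c(1L, 2L), c(1.2, 0.8)), 1L)
  expect_equal(avalanchr:::pick_bin_by_sigma(c(2L, 4L), c(NA, 0.9)), 4L)
  # and select_bin_size() applies exactly that rule to measured sigmas
  model <- make_propagation_model(20, density = 0.5, target_rho = 1, seed = 2)
  raster <- simulate_raster(model, 8000, seed = 3)
  cands <- c(1L, 2L, 4L)
  sig <- vapply(cands, function(b)
    branching_ratio(detect_avalanches(rebin(raster, b), 1))$sigma, numeric(1))
  expect_equal(select_bin_size(raster, cands, 1),
               avalanchr:::pick_bin_by_sigma(cands, sig))
})

test_that("bin selection warns on empty candidates and errors when all fail", {
  # a raster whose only activity touches the edges yields no avalanche
  r <- raster_from_bits(rbind(c(1, 0, 0, 1), c(0, 0, 0, 0)))
  expect_error(suppressWarnings(select_bin_size(r, c(1L, 2L), 1)),
               "no candidate")
  # mixed: candidate 4 collapses an 8-bin segment to 2 empty-edge bins
  bits <- rbind(c(0, 1, 1, 0, 0, 1, 1, 0), rep(0, 8))
  r2 <- raster_from_bits(bits)
  expect_warning(got <- select_bin_size(r2, c(1L, 4L), 1), "skipped")
  expect_equal(got, 1L)
})
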