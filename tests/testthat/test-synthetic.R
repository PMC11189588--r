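test_that("propagation models are reproducible and respect density", {
  m1 <- make_propagation_model(10, density = 1, target_rho = 1, seed = 3)
  offd <- row(m1$graph) != col(m1$graph)
  expect_true(all(m1$graph[offd] > 0))
  expect_true(all(diag(m1$graph) == 0))
  m2 <- make_propagation_model(10, density = 1, target_rho = 1, seed = 3)
  expect_identical(m1$graph, m2$graph)
  m3 <- make_propagation_model(10, density = 1, target_rho = 1, seed = 4)
  expect_false(identical(m1$graph, m3$graph))
  # row sums over active rows average to rho
  expect_equal(mean(rowSums(m1$graph)), 1, tolerance = 1e-12)
  expect_error(make_propagation_model(5, density = 0, target_rho = 1), "density")
  expect_error(make_propagation_model(5, density = 0.5, target_rho = -1), "positive")
})

test_that("raster simulation honours drive, graph and determinism", {
  m <- make_propagation_model(4, density = 1, target_rho = 1, seed = 1,
                              drive_rate = 0)
  r <- simulate_raster(m, 200, seed = 2)
  expect_false(any(r$bits))  # no drive, no seeds, silence forever

  # single ROI, no propagation, certain drive: seed then refractory silence
  m2 <- make_propagation_model(2, density = 1, target_rho = 0.001, seed = 1,
                               drive_rate = 1)
  m2$graph[] <- 0
  r2 <- simulate_raster(m2, 50, seed = 3)
  expect_true(all(colSums(r2$bits) > 0 | colSums(r2$bits) == 0))
  # with drive 1 and refractory 1 the network alternates active/silent
  occ <- colSums(r2$bits) > 0
  expect_identical(unname(occ), rep(c(TRUE, FALSE), 25))

  r3 <- simulate_raster(m, 300, seed = 7)
  r4 <- simulate_raster(m, 300, seed = 7)
  expect_identical(r3$bits, r4$bits)
})

test_that("sub- and supercritical regimes order the sigma estimate", {
  sig <- vapply(c(0.5, 1.5), function(rho) {
    m <- make_propagation_model(30, density = 0.5, target_rho = rho, seed = 11)
    r <- simulate_raster(m, 40000, seed = 12)
    est <- branching_ratio(detect_avalanches(r, 2))
    expect_gte(est$n_avalanches, 300)
    est$sigma
  }, numeric(1))
  expect_lt(sig[1], 1)
  expect_gt(sig[2], 1)
  expect_lt(sig[1], sig[2])
})

test_that("noiseless rendering round-trips the raster exactly", {
  m <- make_propagation_model(6, density = 0.5, target_rho = 1, seed = 21)
  r <- simulate_raster(m, 3000, seed = 22)
  ts <- raster_to_timeseries(r, noise_sd = 0, seed = 23)
  # threshold below the pulse z-height: pulses are the only nonzero samples
  q <- rowMeans(r$bits)
  thr <- 0.9 / sqrt(max(q))  # below every ROI's pulse height 1/sqrt(q_r)
  rec <- binarize(ts, thr)
  expect_identical(unname(rec$bits), unname(r$bits))

  ts2 <- raster_to_timeseries(r, noise_sd = 0, seed = 23)
  expect_identical(ts$data, ts2$data)
})

test_that("default rendering keeps the round trip sensitive and specific", {
  m <- make_propagation_model(20, density = 0.5, target_rho = 1, seed = 31)
  r <- simulate_raster(m, 30000, seed = 32)
  ts <- raster_to_timeseries(r, seed = 33)  # calibrated, burst z 2.5
  rec <- binarize(ts, 2.0)  # burst_amplitude_z - 0.5
  tp <- sum(rec$bits & r$bits); fn <- sum(!rec$bits & r$bits)
  fp <- sum(rec$bits & !r$bits); tn <- sum(!rec$bits & !r$bits)
  expect_gte(tp / (tp + fn), 0.9)   # sensitivity
  expect_gte(tn / (tn + fp), 0.95)  # specificity
})

test_that("pulse peaks land near the requested z-height under calibration", {
  m <- make_propagation_model(10, density = 0.5, target_rho = 1, seed = 41)
  r <- simulate_raster(m, 20000, seed = 42)
  for (bz in c(2.0, 2.5, 3.0)) {
    ts <- raster_to_timeseries(r, burst_amplitude_z = bz, seed = 43)
    z <- (ts$data - rowMeans(ts$data)) / apply(ts$data, 1, sd)
    peak <- median(abs(z[which(r$bits)]))
    expect_equal(peak, bz, tolerance = 0.05)
  }
})

test_that("cohorts are reproducible, labelled, and exchangeable at null effect", {
  spec <- cohort_spec(n_per_group = 2, n_rois = 8, duration_s = 8, fs = 250,
                      effect_size = 0, seed = 5)
  c1 <- make_cohort(spec)
  c2 <- make_cohort(spec)
  expect_identical(c1$subjects[[1]]$data, c2$subjects[[1]]$data)
  expect_identical(c1$manifest$group, c(rep("A", 2), rep("B", 2)))
  # effect 0: both groups share the same generative graph
  expect_identical(c1$models$A$graph, c1$models$B$graph)

  spec2 <- cohort_spec(n_per_group = 2, n_rois = 8, duration_s = 8, fs = 250,
                       effect_size = 0.5, seed = 5)
  c3 <- make_cohort(spec2)
  # rewiring preserves the weight multiset but moves edges
  gA <- c3$models$A$graph; gB <- c3$models$B$graph
  expect_false(identical(gA, gB))
  expect_equal(sort(gA[gA > 0]), sort(gB[gB > 0]))
  n_moved <- sum(gA > 0 & gB == 0)
  expect_equal(n_moved, round(0.5 * sum(gA > 0)))
})
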