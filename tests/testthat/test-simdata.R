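test_that("trial design has the counterbalanced off-cardinal orientation sets", {
  d1 <- generateDesign(1L, seed = 7)
  tg <- sort(d1$target_deg)
  expect_equal(tg, 1.125 + 4.5 * (0:39))
  expect_equal(range(tg), c(1.125, 176.625))
  expect_equal(unique(round(diff(tg), 10)), 4.5)
  ds <- sort(d1$distractor_deg)
  expect_equal(range(ds), c(3.375, 178.875))
  # disjoint sets, no exact cardinals
  expect_length(intersect(d1$target_deg, d1$distractor_deg), 0)
  expect_false(any(c(d1$target_deg, d1$distractor_deg) %in% c(0, 45, 90, 135)))

  d8 <- generateDesign(8L, seed = 8)
  expect_equal(nrow(d8), 320L)
  expect_true(all(table(d8$target_deg) == 8L))
  # exactly flat per-run histograms for any run count
  for (r in unique(d8$run)) {
    expect_true(all(table(d8$target_deg[d8$run == r]) == 1L))
    expect_true(all(table(d8$distractor_deg[d8$run == r]) == 1L))
  }
  expect_true(all(d8$cue %in% 1:2))
  expect_identical(generateDesign(3L, seed = 5), generateDesign(3L, seed = 5))
})

test_that("periodic kernel matches its closed form and is a valid covariance", {
  expect_equal(periodicKernel(0.7, 0.7, 0.7), 1)
  expect_equal(periodicKernel(0, pi, 1), exp(-2), tolerance = 1e-12)
  set.seed(42)
  a <- runif(20, 0, 2 * pi); b <- runif(20, 0, 2 * pi)
  expect_equal(periodicKernel(a, b, 0.9), periodicKernel(b, a, 0.9))
  expect_equal(periodicKernel(a + 2 * pi, b, 0.9), periodicKernel(a, b, 0.9))
  expect_true(all(periodicKernel(a, b, 2) > 0 & periodicKernel(a, b, 2) <= 1))
  expect_error(periodicKernel(0, 1, 0), "positive")

  # PSD on a 40-point grid for gamma-drawn smoothness, before jitter
  grid <- seq(0, 2 * pi, length.out = 41)[1:40]
  set.seed(11)
  for (s in rgamma(20, shape = 2, scale = 2)) {
    K <- outer(grid, grid, periodicKernel, sigma = s)
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("tuning profiles are reproducible with unit marginal variance", {
  p1 <- sampleTuningProfiles(5, 64, seed = 3)
  p2 <- sampleTuningProfiles(5, 64, seed = 3)
  expect_identical(p1, p2)
  expect_length(p1, 5L)
  expect_length(p1[[1]]$values, 64L)
  expect_true(all(vapply(p1, function(x) x$smoothness, numeric(1)) > 0))

  # K(x, x) = 1 implies unit variance at every grid point
  big <- sampleTuningProfiles(1000, 32, seed = 4)
  z1 <- vapply(big, function(p) p$values[1L], numeric(1))
  z17 <- vapply(big, function(p) p$values[17L], numeric(1))
  expect_equal(var(z1), 1, tolerance = 0.15)
  expect_equal(var(z17), 1, tolerance = 0.15)
})

test_that("voxel responses follow y = r*s + eps", {
  design <- generateDesign(2L, seed = 1)
  prof <- sampleTuningProfiles(50, 90, seed = 2)

  # s = 0: pure standard-normal noise
  null <- simulateVoxelResponses(prof, design, snr = 0, seed = 3)
  vals <- do.call(rbind, voxelData(null))
  expect_equal(mean(vals), 0, tolerance = 0.05)
  expect_equal(var(as.vector(vals)), 1, tolerance = 0.05)

  # determinism
  a <- simulateVoxelResponses(prof, design, snr = 1, seed = 9)
  b <- simulateVoxelResponses(prof, design, snr = 1, seed = 9)
  expect_identical(voxelData(a), voxelData(b))

  # signal part is the tuning value at the trial orientation
  noise <- do.call(rbind, voxelData(null))
  sig <- do.call(rbind, voxelData(simulateVoxelResponses(prof, design,
                                                         snr = 1, seed = 3)))
  d1 <- design[order(design$run, design$trial), ]
  idx <- round(2 * pi * d1$target_deg[1] / 180 / (2 * pi / 90)) %% 90 + 1
  expect_equal(sig[1, 1] - noise[1, 1], prof[[1]]$values[idx],
               tolerance = 1e-10)

  bad <- design; bad$target_deg[1] <- 200
  expect_error(simulateVoxelResponses(prof, bad, 1, seed = 1), "0, 180")
})

test_that("timecourse expansion confines the pattern to the active window", {
  ds <- simulateVoxelDataset(nRuns = 2L, nVoxels = 20L, snr = 1, seed = 6)
  tc <- expandToTimecourse(ds$series, trsPerTrial = 8L, activeWindow = 3:5,
                           seed = 7)
  expect_equal(seriesLayout(tc), "timecourse")
  expect_equal(nRuns(tc), 2L)
  expect_equal(lengths(trialOnsets(tc)), lengths(trialOnsets(ds$series)))
  m <- voxelData(tc)[[1]]
  expect_equal(nrow(m), 40L * 8L)
  # active TRs replicate the trial pattern exactly
  trial1 <- voxelData(ds$series)[[1]][1, ]
  for (tr in 3:5) expect_equal(m[tr, ], trial1)
  # outside the window the rows differ from the pattern
  expect_gt(sum(abs(m[1, ] - trial1)), 0)
  expect_error(expandToTimecourse(ds$series, 8L, integer(0)), "at least one")
  expect_error(expandToTimecourse(ds$series, 8L, 7:10), "within")
})

test_that("behavioural simulation honours the mixture components", {
  d <- generateDesign(8L, seed = 1)

  # degenerate detection: huge precision pins responses to the target
  pin <- simulateBehavior(d, VMMMParams(1, 0, 0, kappa1 = 1e6), seed = 2)
  expect_lt(max(abs(circDiff180(pin$response_deg, pin$target_deg))), 0.5)

  # guess-only: response errors uniform on [-90, 90)
  dBig <- do.call(rbind, replicate(32, d, simplify = FALSE))
  g <- simulateBehavior(dBig, VMMMParams(0, 0, 1, kappa1 = 1), seed = 3)
  err <- circDiff180(g$response_deg, g$target_deg)
  ks <- suppressWarnings(stats::ks.test(err, "punif", -90, 90))
  expect_gt(ks$p.value, 0.01)

  expect_identical(simulateBehavior(d, VMMMParams(0.9, 0.05, 0.05, 5), seed = 4),
                   simulateBehavior(d, VMMMParams(0.9, 0.05, 0.05, 5), seed = 4))
})

test_that("design and voxel series round-trip through their file formats", {
  ds <- simulateVoxelDataset(nRuns = 2L, nVoxels = 10L, snr = 0.5, seed = 8)
  tmp <- tempfile(fileext = ".tsv")
  writeDesignTsv(ds$design, tmp)
  back <- readDesignTsv(tmp)
  expect_equal(back$target_deg, ds$design$target_deg)

  bin <- tempfile()
  writeVoxelSeries(ds$series, bin)
  rs <- readVoxelSeries(bin)
  expect_equal(voxelData(rs), voxelData(ds$series))
  expect_equal(seriesLayout(rs), "trialwise")
  unlink(c(tmp, bin, paste0(bin, ".json")))
})
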