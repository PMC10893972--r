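test_that("spline detrending removes slow drifts but spares trial-locked signal", {
  # constant series: spline reproduces the constant exactly
  const <- matrix(5, 200, 3)
  out <- splineDetrend(const, nTrials = 40L)
  expect_equal(max(abs(out)), 0, tolerance = 1e-10)
  expect_equal(attr(out, "nNodes"), 20L)

  # pure linear drift: interpolating spline through collinear nodes is the
  # line itself
  tp <- 800L
  drift <- matrix(seq(0, 10, length.out = tp))
  res <- splineDetrend(drift, nTrials = 40L)
  expect_lt(max(abs(res)), 1e-6 * 10)

  # drift + trial-locked oscillation: half-trial nodes cannot absorb
  # within-trial structure
  locked <- sin(2 * pi * (0:(tp - 1)) / 20)
  series <- matrix(drift + locked)
  res2 <- splineDetrend(series, nTrials = 40L)
  expect_gt(cor(res2[, 1], locked), 0.95)

  # idempotency: once the residual averages to zero within every segment
  # (drift plus segment-periodic signal), a second pass changes nothing
  smooth <- matrix(drift + locked)
  once <- splineDetrend(smooth, 40L)
  twice <- splineDetrend(once, 40L)
  expect_lt(max(abs(twice - once)), 1e-6)

  set.seed(1)
  noisy <- matrix(rnorm(400), 200, 2) + drift[1:200, rep(1, 2)]
  expect_error(splineDetrend(noisy, 39L), "odd")
  expect_equal(attr(splineDetrend(noisy, 39L, nNodes = 10L), "nNodes"), 10L)
  expect_error(splineDetrend(matrix(0, 10, 1), 40L), "too short")
})

test_that("temporal smoothing is a centred moving average with shrinking edges", {
  imp <- matrix(c(0, 0, 1, 0, 0))
  expect_equal(temporalSmooth(imp, 3L)[, 1], c(0, 1/3, 1/3, 1/3, 0))
  const <- matrix(2, 10, 2)
  expect_equal(temporalSmooth(const, 3L), const)
  x <- matrix(rnorm(20), 20, 1)
  expect_equal(temporalSmooth(x, 1L), x)
  expect_error(temporalSmooth(x, 2L), "odd")
  expect_error(temporalSmooth(x, 21L), "exceeds")
})

test_that("trial sample extraction respects onsets and offsets", {
  ds <- makeDecodableSamples(nRuns = 2L, nVoxels = 15L, seed = 2)
  # trialwise, offset 0: identity
  expect_equal(sampleMatrix(ds$samples),
               do.call(rbind, voxelData(ds$series)))
  expect_equal(nrow(sampleMatrix(ds$samples)), 80L)

  d8 <- simulateVoxelDataset(nRuns = 8L, nVoxels = 5L, snr = 0, seed = 3)
  expect_equal(nrow(sampleMatrix(extractTrialSamples(d8$series, d8$design))),
               320L)

  tc <- expandToTimecourse(ds$series, 6L, 2:4, seed = 4)
  s0 <- extractTrialSamples(tc, ds$design, trOffset = 1L)  # second TR
  expect_equal(sampleMatrix(s0)[1, ], voxelData(ds$series)[[1]][1, ])
  expect_error(extractTrialSamples(tc, ds$design, trOffset = 240L), "beyond")
  expect_error(extractTrialSamples(ds$series, ds$design, 1L), "trialwise")
})

test_that("feature-space smoothing is a convex within-run average", {
  ds <- makeDecodableSamples(nRuns = 2L, nVoxels = 12L, seed = 5)
  expect_identical(featureSpaceSmooth(ds$samples, 0), ds$samples)
  expect_error(featureSpaceSmooth(ds$samples, -1), "nonnegative")

  # identical rows stay identical for any width (convex combination)
  X <- matrix(rep(seq_len(12), each = 80), 80, 12)
  same <- TrialSamples(X, trialDesign(ds$samples))
  for (fw in c(10, 60, 180))
    expect_equal(sampleMatrix(featureSpaceSmooth(same, fw)), X,
                 tolerance = 1e-12)

  # balanced labels: per-voxel grand mean preserved (doubly stochastic
  # weights)
  sm <- featureSpaceSmooth(ds$samples, 45)
  expect_equal(colMeans(sampleMatrix(sm)),
               colMeans(sampleMatrix(ds$samples)), tolerance = 1e-10)

  # within-run scope: smoothing one run never touches another
  X2 <- sampleMatrix(ds$samples)
  X2[trialRuns(ds$samples) == 2L, ] <- 1e6
  spiked <- TrialSamples(X2, trialDesign(ds$samples))
  out <- sampleMatrix(featureSpaceSmooth(spiked, 60))
  expect_equal(out[trialRuns(ds$samples) == 1L, ],
               sampleMatrix(featureSpaceSmooth(ds$samples, 60))[
                 trialRuns(ds$samples) == 1L, ],
               tolerance = 1e-9)
})

test_that("feature-space smoothing raises decoding accuracy at moderate SNR", {
  diffs <- vapply(1:12, function(rep) {
    ds <- simulateVoxelDataset(nRuns = 4L, nVoxels = 100L, snr = 0.3,
                               seed = 500 + rep)
    samp <- extractTrialSamples(ds$series, ds$design, 0L)
    a0 <- bfca(trialLabels(samp, "target"), loroCv(samp))
    sm <- featureSpaceSmooth(samp, 60)
    a60 <- bfca(trialLabels(sm, "target"), loroCv(sm))
    a60 - a0
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("voxel selection takes the top scores with stable tie-breaking", {
  expect_equal(selectVoxels(c(3, 1, 2), 2L), c(1L, 3L))
  expect_equal(sort(selectVoxels(rnorm(10), 10L)), 1:10)
  ties <- c(1, 2, 2, 2, 0)
  expect_equal(selectVoxels(ties, 3L), c(2L, 3L, 4L))
  expect_identical(selectVoxels(ties, 3L), selectVoxels(ties, 3L))
  expect_error(selectVoxels(ties, 0L), "positive")
  expect_error(selectVoxels(ties, 9L), "exceeds")
})
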