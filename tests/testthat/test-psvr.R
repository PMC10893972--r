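test_that("sinusoid encoding and atan2 decoding are inverse maps", {
  enc <- encodeLabels(c(0, 45, 90))
  expect_equal(enc[, "x"], c(0, 1, 0), tolerance = 1e-12)
  expect_equal(enc[, "y"], c(1, 0, -1), tolerance = 1e-12)
  expect_equal(decodeLabels(0, 1), 0)
  expect_equal(decodeLabels(1, 0), 45)

  set.seed(1)
  theta <- runif(1000, 0, 180)
  e <- encodeLabels(theta)
  expect_equal(decodeLabels(e[, "x"], e[, "y"]), theta, tolerance = 1e-9)
  expect_true(all(abs(e[, "x"]^2 + e[, "y"]^2 - 1) < 1e-12))
  expect_error(decodeLabels(0, 0), "zero vector")
  expect_error(encodeLabels(180), "0, 180")
})

test_that("across-scaling maps train to [0,1] and reuses train parameters", {
  train <- cbind(c(2, 4), c(7, 7))
  test <- cbind(c(3, 6), c(1, 9))
  sc <- scaleAcross(train, test)
  expect_equal(sc$train[, 1], c(0, 1))
  expect_equal(sc$test[, 1], c(0.5, 2))     # test may leave [0, 1]
  expect_equal(sc$train[, 2], c(0, 0))      # constant train feature -> 0
  expect_equal(sc$test[, 2], c(0, 0))
  expect_error(scaleAcross(train, test[, 1, drop = FALSE]), "differ")
})

test_that("the SVR pair reconstructs a noise-free toy on its training data", {
  toy <- makeNoiseFreeToy(2L)
  pp <- fitPredictPair(toy$X, toy$theta, toy$X)
  err <- abs(circDiff180(decodeLabels(pp[, "x"], pp[, "y"]), toy$theta))
  expect_lt(mean(err), 5)
})

test_that("decoding is equivariant under label rotation", {
  toy <- makeNoiseFreeToy(4L)
  base <- fitPredictPair(toy$X, toy$theta, toy$X)
  b <- decodeLabels(base[, "x"], base[, "y"])
  for (delta in c(4.5, 45)) {
    rot <- fitPredictPair(toy$X, wrap180(toy$theta + delta), toy$X)
    r <- decodeLabels(rot[, "x"], rot[, "y"])
    expect_lt(max(abs(circDiff180(r, wrap180(b + delta)))), 1)
  }
})

test_that("uninformative features give constant predictions with a warning", {
  X <- matrix(1, 20, 5)
  theta <- rep(1.125 + 4.5 * (0:9), 2)
  pp <- fitPredictPair(X, theta, X)
  expect_lt(max(abs(pp[, "x"] - pp[1, "x"])), 1e-9)
  expect_lt(max(abs(pp[, "y"] - pp[1, "y"])), 1e-9)
  w <- capture_warnings(fitPredictPair(X, rep(10, 20), X))
  expect_length(w, 2L)   # one per sinusoid component
  expect_match(w, "degenerate", all = TRUE)
})

test_that("leave-one-run-out folds predict every trial exactly once", {
  ds <- makeDecodableSamples(nRuns = 8L, nVoxels = 30L, snr = 0.8, seed = 7)
  pred <- loroCv(ds$samples)
  expect_length(pred, 320L)
  expect_true(all(pred >= 0 & pred < 180))
  expect_identical(loroCv(ds$samples), pred)
  one <- TrialSamples(sampleMatrix(ds$samples)[trialRuns(ds$samples) == 1L, ],
                      trialDesign(ds$samples)[trialRuns(ds$samples) == 1L, ])
  expect_error(loroCv(one), "at least 2 runs")
})

test_that("test folds never inform training: per-run relabelling only moves its own fold", {
  # relabel run 1 only; predictions for the other runs come from models
  # whose training set changed, but run 1's own fold (trained on runs
  # 2..4, unchanged) must predict identically from identical features
  ds <- makeDecodableSamples(nRuns = 4L, nVoxels = 25L, snr = 0.8, seed = 8)
  pred <- loroCv(ds$samples)
  d2 <- trialDesign(ds$samples)
  sel <- d2$run == 1L
  d2$target_deg[sel] <- wrap180(d2$target_deg[sel] + 31)
  relab <- TrialSamples(sampleMatrix(ds$samples), d2)
  pred2 <- loroCv(relab)
  expect_equal(pred2[sel], pred[sel])
  expect_false(isTRUE(all.equal(pred2[!sel], pred[!sel])))
})

test_that("decoding permuted labels sits at chance", {
  ds <- makeDecodableSamples(nRuns = 4L, nVoxels = 80L, snr = 1, seed = 9)
  set.seed(10)
  acc <- vapply(1:10, function(i) {
    d2 <- trialDesign(ds$samples)
    d2$target_deg <- sample(d2$target_deg)
    perm <- TrialSamples(sampleMatrix(ds$samples), d2)
    bfca(trialLabels(perm, "target"), loroCv(perm))
  }, numeric(1))
  expect_gt(mean(acc), 46)
  expect_lt(mean(acc), 54)
})

test_that("time-resolved reconstruction finds information only in the active window", {
  ds <- simulateVoxelDataset(nRuns = 3L, nVoxels = 60L, snr = 1, seed = 11)
  tc <- expandToTimecourse(ds$series, trsPerTrial = 8L, activeWindow = 3:5,
                           seed = 12)
  rec <- reconstructTimecourse(tc, ds$design, fwhmDeg = 0, nTRs = 8L)
  bf <- bfcaTimecourse(rec)
  expect_length(bf, 8L)
  expect_equal(dim(predictedOrientations(rec)), c(8L, 120L))
  expect_gt(mean(bf[3:5]), 65)          # strong signal inside the window
  expect_lt(mean(bf[c(1, 2, 7, 8)]), 56)  # chance outside it

  # an undecoded label (distractor never drove the voxels) stays at chance
  recD <- reconstructTimecourse(tc, ds$design, fwhmDeg = 0,
                                labelKindArg = "distractor", nTRs = 8L)
  expect_lt(max(abs(bfcaTimecourse(recD) - 50)), 8)

  tmp <- tempfile(fileext = ".tsv")
  writeTimecourseTsv(rec, tmp)
  tab <- read.delim(tmp)
  expect_equal(nrow(tab), 8L * 120L)
  unlink(tmp)
})
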