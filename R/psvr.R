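#' Encode orientations as a pair of sinusoid labels
#'
#' Projects 180-degree-periodic orientations into a periodic label space:
#' two sinusoids of amplitude 1 and period 180 degrees, phase-shifted by
#' 45 degrees, jointly code the angle the way sine and cosine code a
#' 360-degree angle. Concretely x = sin(2 theta pi / 180) and
#' y = cos(2 theta pi / 180).
#'
#' @param theta orientations in degrees, [0, 180).
#' @return matrix with columns \code{x} and \code{y}, each in [-1, 1].
#' @export
#' @examples
#' encodeLabels(c(0, 45, 90))
encodeLabels <- function(theta) {
  if (any(theta < 0 | theta >= 180))
    stop("orientations must lie in [0, 180)")
  phi <- theta * pi / 90
  cbind(x = sin(phi), y = cos(phi))
}

#' Recover an orientation from a predicted sinusoid pair
#'
#' Four-quadrant inverse tangent recombination: theta-hat =
#' atan2(x-hat, y-hat) mapped back from the doubled-angle scale into
#' [0, 180). Predicted pairs need not lie on the unit circle and are used
#' as-is (atan2 only needs the direction).
#'
#' @param x,y predicted sinusoid components (vectorized).
#' @return orientations in degrees, [0, 180).
#' @export
#' @examples
#' decodeLabels(1, 0)  # 45
decodeLabels <- function(x, y) {
  if (any(x == 0 & y == 0)) stop("zero vector has no defined angle")
  wrap180((atan2(x, y) %% (2 * pi)) * 90 / pi)
}

#' Decoder hyperparameters
#'
#' Settings of the two epsilon-insensitive RBF-kernel support vector
#' regressions at the decoder's core. The RBF width defaults to
#' 1 / (n_features * var(training data)), computed inside each training
#' fold (never from test data).
#'
#' @param cost SVR cost parameter C (> 0).
#' @param epsilonTube width of the epsilon-insensitive tube (>= 0).
#' @param rbfGamma RBF kernel gamma; \code{NULL} (default) applies the
#'   fold-wise variance rule.
#' @return a list of class \code{"DecoderSpec"}.
#' @export
decoderSpec <- function(cost = 1, epsilonTube = 0.1, rbfGamma = NULL) {
  if (cost <= 0) stop("cost must be positive")
  if (epsilonTube < 0) stop("epsilonTube must be nonnegative")
  structure(list(cost = cost, epsilonTube = epsilonTube,
                 rbfGamma = rbfGamma), class = "DecoderSpec")
}

#' Across-scaling of train and test features
#'
#' Rescales every feature of the training data to [0, 1] (subtract the
#' training minimum, divide by the training range) and applies the same
#' parameters to the test data, whose values may therefore leave [0, 1].
#' Features constant in training map to 0 in both sets.
#'
#' @param train,test numeric matrices (rows = trials) with matching
#'   feature counts.
#' @return list with scaled \code{train} and \code{test} matrices.
#' @export
scaleAcross <- function(train, test) {
  train <- as.matrix(train); test <- as.matrix(test)
  if (ncol(train) != ncol(test)) stop("feature counts differ")
  mins <- apply(train, 2L, min)
  rng <- apply(train, 2L, max) - mins
  const <- rng == 0
  rng[const] <- 1
  sc <- function(m) {
    out <- sweep(sweep(m, 2L, mins, "-"), 2L, rng, "/")
    out[, const] <- 0
    out
  }
  list(train = sc(train), test = sc(test))
}

#' Fit the periodic SVR pair and predict test labels
#'
#' Trains two independent epsilon-insensitive support vector regressions
#' with RBF kernel (the LIBSVM implementation via \pkg{e1071}), one per
#' sinusoid component, on the scaled training data, and predicts both
#' components for the test trials. Predictions are left unclipped.
#'
#' @param train,test scaled feature matrices (rows = trials).
#' @param trainTheta training orientations in degrees, [0, 180).
#' @param spec a \code{\link{decoderSpec}}.
#' @return matrix of predicted components, columns \code{x} and \code{y}.
#' @export
fitPredictPair <- function(train, trainTheta, test, spec = decoderSpec()) {
  train <- as.matrix(train); test <- as.matrix(test)
  if (nrow(train) < 2L) stop("at least two training trials required")
  if (ncol(train) != ncol(test)) stop("feature counts differ")
  enc <- encodeLabels(trainTheta)
  gamma <- spec$rbfGamma
  if (is.null(gamma)) {
    v <- var(as.vector(train))
    gamma <- if (is.finite(v) && v > 0) 1 / (ncol(train) * v) else
      1 / ncol(train)
  }
  pred <- matrix(NA_real_, nrow(test), 2L,
                 dimnames = list(NULL, c("x", "y")))
  for (k in 1:2) {
    if (sd(enc[, k]) < 1e-12) {
      warning("degenerate training labels (component ", colnames(enc)[k],
              " constant); predicting the constant")
      pred[, k] <- enc[1L, k]
      next
    }
    m <- e1071::svm(x = train, y = enc[, k], type = "eps-regression",
                    kernel = "radial", cost = spec$cost,
                    epsilon = spec$epsilonTube, gamma = gamma,
                    scale = FALSE)
    pred[, k] <- as.numeric(predict(m, test))
  }
  pred
}

#' Leave-one-run-out cross-validated orientation decoding
#'
#' For each run, the decoder is trained on all remaining runs (with
#' across-scaling fitted on those training runs only) and predicts the
#' held-out run; every trial is predicted exactly once, by a model that
#' never saw it.
#'
#' @param samples a \linkS4class{TrialSamples} (already feature-space
#'   smoothed if desired; smoothing is per-run, so it introduces no fold
#'   leakage).
#' @param spec a \code{\link{decoderSpec}}.
#' @param labelKindArg which label to decode (default \code{"target"}).
#' @return numeric vector of predicted orientations in degrees, aligned
#'   with the trials of \code{samples}.
#' @export
loroCv <- function(samples, spec = decoderSpec(), labelKindArg = "target") {
  X <- sampleMatrix(samples)
  theta <- trialLabels(samples, labelKindArg)
  runs <- trialRuns(samples)
  uruns <- unique(runs)
  if (length(uruns) < 2L)
    stop("leave-one-run-out cross-validation needs at least 2 runs")
  pred <- numeric(nrow(X))
  for (r in uruns) {
    te <- runs == r
    sc <- scaleAcross(X[!te, , drop = FALSE], X[te, , drop = FALSE])
    pp <- fitPredictPair(sc$train, theta[!te], sc$test, spec)
    pred[te] <- decodeLabels(pp[, "x"], pp[, "y"])
  }
  pred
}

#' Time-resolved orientation reconstruction
#'
#' Runs extract -> feature-space smooth -> leave-one-run-out decode at
#' every TR offset following trial (delay) onset, giving a time-resolved
#' picture of when the requested orientation label is represented in the
#' voxel pattern. Per-TR balanced accuracy (BFCA) is computed against the
#' decoded label.
#'
#' @param series a timecourse-layout (or trialwise, with \code{nTRs = 1})
#'   \linkS4class{VoxelSeries}.
#' @param design aligned trial table.
#' @param spec a \code{\link{decoderSpec}}.
#' @param fwhmDeg feature-space smoothing kernel FWHM in degrees.
#' @param labelKindArg label to decode: \code{"target"},
#'   \code{"distractor"}, \code{"probe_start"} or \code{"report"}.
#' @param nTRs number of TR offsets to decode (default 30, i.e. 24 s at a
#'   0.8-s TR).
#' @param subject subject identifier carried into the result.
#' @return a \linkS4class{ReconstructionTimecourse}.
#' @export
reconstructTimecourse <- function(series, design, spec = decoderSpec(),
                                  fwhmDeg = 0, labelKindArg = "target",
                                  nTRs = 30L, subject = "sim01") {
  nTRs <- as.integer(nTRs)
  pred <- NULL
  truth <- NULL
  runsVec <- NULL
  bf <- numeric(nTRs)
  for (tr in seq_len(nTRs)) {
    samp <- extractTrialSamples(series, design, trOffset = tr - 1L)
    samp <- featureSpaceSmooth(samp, fwhmDeg)
    if (is.null(pred)) {
      truth <- trialLabels(samp, labelKindArg)
      runsVec <- trialRuns(samp)
      pred <- matrix(NA_real_, nTRs, length(truth))
    }
    pred[tr, ] <- loroCv(samp, spec, labelKindArg)
    bf[tr] <- bfca(truth, pred[tr, ])
  }
  new("ReconstructionTimecourse", predicted = pred, truth = truth,
      runs = as.integer(runsVec), labelKind = labelKindArg,
      bfcaByTR = bf, subject = subject)
}

#' Write per-TR predictions as TSV
#'
#' @param tc a \linkS4class{ReconstructionTimecourse}.
#' @param path output path.
#' @export
writeTimecourseTsv <- function(tc, path) {
  p <- predictedOrientations(tc)
  df <- data.frame(
    subject = tc@subject,
    tr = rep(seq_len(nrow(p)), each = ncol(p)),
    trial = rep(seq_len(ncol(p)), nrow(p)),
    run = rep(tc@runs, nrow(p)),
    label_kind = tc@labelKind,
    true_deg = rep(tc@truth, nrow(p)),
    predicted_deg = as.vector(t(p))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
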