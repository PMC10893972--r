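#' Cubic-spline temporal detrending of one run
#'
#' Removes slow signal drifts: the run is split into nTrials/2 segments of
#' (near-)equal length, each segment is averaged per voxel to form a node
#' at the segment centre, an interpolating natural cubic spline through
#' the nodes models the drift, and the spline is subtracted. The node
#' count is deliberately half the trial count so that within-trial signal
#' structure cannot be absorbed into (and removed with) the drift
#' estimate.
#'
#' @param runSeries numeric matrix, timepoints x voxels, of one run.
#' @param nTrials number of trials in the run; must be even (for an odd
#'   trial count pass \code{nNodes} explicitly).
#' @param nNodes optional explicit node count, overriding nTrials/2.
#' @return detrended matrix of the same shape, with attribute
#'   \code{"nNodes"} recording the node count used.
#' @export
splineDetrend <- function(runSeries, nTrials, nNodes = NULL) {
  runSeries <- as.matrix(runSeries)
  nT <- nrow(runSeries)
  if (is.null(nNodes)) {
    if (nTrials %% 2L != 0L)
      stop("nTrials is odd; the nTrials/2 node rule is undefined - ",
           "pass an explicit node count via nNodes")
    nNodes <- nTrials %/% 2L
  }
  nNodes <- as.integer(nNodes)
  if (nT < 2L * nNodes)
    stop("run too short: need at least ", 2L * nNodes, " timepoints for ",
         nNodes, " nodes")
  bounds <- round(seq(0, nT, length.out = nNodes + 1L))
  segIdx <- lapply(seq_len(nNodes), function(k) (bounds[k] + 1L):bounds[k + 1L])
  nodeX <- vapply(segIdx, function(ix) mean(ix), numeric(1))
  out <- runSeries
  for (v in seq_len(ncol(runSeries))) {
    nodeY <- vapply(segIdx, function(ix) mean(runSeries[ix, v]), numeric(1))
    drift <- spline(nodeX, nodeY, xout = seq_len(nT), method = "natural")$y
    out[, v] <- runSeries[, v] - drift
  }
  attr(out, "nNodes") <- nNodes
  out
}

#' Temporal moving-average smoothing of one run
#'
#' Centred moving average of odd width per voxel; the window shrinks at
#' the run edges (average over the available neighbours), so the output
#' has the same length and no padding artifacts.
#'
#' @param runSeries numeric matrix, timepoints x voxels.
#' @param width odd window width in TRs (default 3).
#' @return smoothed matrix of the same shape.
#' @export
#' @examples
#' temporalSmooth(matrix(c(0, 0, 1, 0, 0)), width = 3)
temporalSmooth <- function(runSeries, width = 3L) {
  runSeries <- as.matrix(runSeries)
  width <- as.integer(width)
  if (width < 1L || width %% 2L == 0L)
    stop("width must be odd and at least 1")
  if (width > nrow(runSeries))
    stop("width exceeds the number of timepoints")
  if (width == 1L) return(runSeries)
  apply(runSeries, 2L, movingAverage, width = width)
}

#' Extract one multivoxel pattern per trial at a fixed TR offset
#'
#' For a timecourse-layout series, takes the voxel vector at (trial onset
#' + trOffset) for every trial; for a trialwise series, offset 0 returns
#' the trial rows unchanged. Offsets are 0-based: offset 0 is the onset TR
#' itself.
#'
#' @param series a \linkS4class{VoxelSeries}.
#' @param design trial table aligned with the series (rows ordered by run,
#'   then trial).
#' @param trOffset 0-based TR offset from trial onset.
#' @return a \linkS4class{TrialSamples}.
#' @export
extractTrialSamples <- function(series, design, trOffset = 0L) {
  trOffset <- as.integer(trOffset)
  if (trOffset < 0L) stop("trOffset must be nonnegative")
  design <- design[order(design$run, design$trial), , drop = FALSE]
  runs <- unique(design$run)
  if (length(runs) != nRuns(series))
    stop("design runs do not match the series")
  if (seriesLayout(series) == "trialwise" && trOffset > 0L)
    stop("trOffset must be 0 for a trialwise series")
  rows <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    d <- design[design$run == runs[i], , drop = FALSE]
    on <- trialOnsets(series)[[i]]
    if (nrow(d) != length(on))
      stop("design trial count does not match onsets in run ", runs[i])
    idx <- on + trOffset
    if (any(idx > nrow(voxelData(series)[[i]])))
      stop("trOffset ", trOffset, " falls beyond the end of run ", runs[i])
    rows[[i]] <- voxelData(series)[[i]][idx, , drop = FALSE]
  }
  TrialSamples(do.call(rbind, rows), design)
}

#' Feature-space smoothing of trial samples
#'
#' Replaces each trial's voxel vector by a Gaussian-weighted average of
#' the vectors of trials with nearby orientations: weights are Gaussian in
#' the circular orientation distance (period 180 degrees) between the
#' trials' target orientations, with sigma = FWHM / sqrt(8 ln 2), and are
#' normalized to sum to 1 per trial. Neighbouring orientations evoke
#' similar voxel patterns, so this averaging suppresses noise without
#' introducing information; with FWHM = 0 the data are returned unchanged.
#'
#' By default averaging pools only trials of the same run, so
#' leave-one-run-out decoding folds never share smoothed information.
#'
#' @param samples a \linkS4class{TrialSamples}.
#' @param fwhmDeg kernel full width at half maximum in degrees (>= 0).
#' @param scope \code{"run"} (default; leakage-safe) or \code{"all"}.
#' @return smoothed \linkS4class{TrialSamples}.
#' @export
featureSpaceSmooth <- function(samples, fwhmDeg, scope = c("run", "all")) {
  scope <- match.arg(scope)
  if (fwhmDeg < 0) stop("FWHM must be nonnegative")
  if (fwhmDeg == 0) return(samples)
  X <- sampleMatrix(samples)
  labels <- trialLabels(samples, "target")
  runs <- trialRuns(samples)
  sigma <- fwhmDeg / sqrt(8 * log(2))
  groups <- if (scope == "run") split(seq_along(labels), runs) else
    list(seq_along(labels))
  out <- X
  for (ix in groups) {
    D <- abs(outer(labels[ix], labels[ix], circDiff180))
    W <- exp(-D^2 / (2 * sigma^2))
    W <- W / rowSums(W)
    out[ix, ] <- W %*% X[ix, , drop = FALSE]
  }
  TrialSamples(out, trialDesign(samples))
}

#' Select the n highest-scoring voxels
#'
#' Standard activation-score voxel selection: returns the indices of the n
#' voxels with the largest scores (e.g. t-scores of a stimulus-versus-
#' baseline contrast). Ties are broken deterministically in favour of the
#' lower index.
#'
#' @param scores numeric per-voxel activation scores.
#' @param n number of voxels to keep.
#' @return integer vector of voxel indices, highest score first.
#' @export
selectVoxels <- function(scores, n) {
  n <- as.integer(n)
  if (n <= 0L) stop("n must be positive")
  if (n > length(scores)) stop("n exceeds the number of voxels")
  ord <- order(-scores, seq_along(scores))
  ord[seq_len(n)]
}
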