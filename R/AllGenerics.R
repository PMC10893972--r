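# Accessors and show methods for the core containers.

#' @describeIn VoxelSeries list of per-run signal matrices.
#' @param x a VoxelSeries.
#' @export
voxelData <- function(x) x@data

#' @describeIn VoxelSeries layout descriptor ("trialwise" or "timecourse").
#' @export
seriesLayout <- function(x) x@layout

#' @describeIn VoxelSeries per-run trial onset indices.
#' @export
trialOnsets <- function(x) x@onsets

#' @describeIn VoxelSeries sampling interval in seconds.
#' @export
trSeconds <- function(x) x@trSeconds

#' @describeIn VoxelSeries number of runs.
#' @export
nRuns <- function(x) length(x@data)

#' @describeIn VoxelSeries number of voxels.
#' @export
nVoxels <- function(x) ncol(x@data[[1L]])

setMethod("show", "VoxelSeries", function(object) {
  cat("VoxelSeries (", object@layout, " layout)\n", sep = "")
  cat("  runs: ", length(object@data),
      ", voxels: ", ncol(object@data[[1L]]),
      ", rows/run: ", paste(vapply(object@data, nrow, integer(1)),
                            collapse = ", "), "\n", sep = "")
  cat("  trials/run: ", paste(lengths(object@onsets), collapse = ", "),
      ", TR: ", object@trSeconds, " s\n", sep = "")
})

#' @describeIn VMMMParams mixture weights (detection, swap, guess).
#' @param x a VMMMParams.
#' @export
mixWeights <- function(x) stats::setNames(x@r, c("r1", "r2", "r3"))

#' @describeIn VMMMParams von Mises precisions (detection, swap).
#' @export
precisions <- function(x) stats::setNames(x@kappa, c("kappa1", "kappa2"))

#' @describeIn VMMMParams response bias in degrees.
#' @export
responseBias <- function(x) x@mu

setMethod("show", "VMMMParams", function(object) {
  cat("von Mises mixture parameters\n")
  cat(sprintf("  r = (%.3f, %.3f, %.3f)  kappa = (%.3f, %.3f)  mu = %.3f deg\n",
              object@r[1], object@r[2], object@r[3],
              object@kappa[1], object@kappa[2], object@mu))
})

#' @describeIn VMMMFit fitted parameters.
#' @param x a VMMMFit.
#' @export
fittedParams <- function(x) x@params

#' @describeIn VMMMFit final log-likelihood of the best restart.
#' @export
fitLogLik <- function(x) x@logLik

#' @describeIn VMMMFit TRUE if a precision sits at the fitting bound.
#' @export
isBoundaryFit <- function(x) x@boundary

setMethod("show", "VMMMFit", function(object) {
  cat("von Mises mixture fit (", object@nRestarts, " restarts)\n", sep = "")
  show(object@params)
  cat(sprintf("  logLik = %.3f, converged = %s%s\n", object@logLik,
              object@converged,
              if (object@boundary) ", precision at bound" else ""))
})

#' @describeIn ReconstructionTimecourse matrix [TR x trial] of decoded
#'   orientations in degrees.
#' @param x a ReconstructionTimecourse.
#' @export
predictedOrientations <- function(x) x@predicted

#' @describeIn ReconstructionTimecourse per-TR balanced accuracy (%).
#' @export
bfcaTimecourse <- function(x) x@bfcaByTR

#' @describeIn ReconstructionTimecourse which label was decoded.
#' @export
labelKind <- function(x) x@labelKind

setMethod("show", "ReconstructionTimecourse", function(object) {
  cat("ReconstructionTimecourse: subject ", object@subject,
      ", label '", object@labelKind, "'\n", sep = "")
  cat("  ", nrow(object@predicted), " TRs x ", ncol(object@predicted),
      " trials; delay BFCA range ",
      sprintf("%.1f-%.1f%%", min(object@bfcaByTR), max(object@bfcaByTR)),
      "\n", sep = "")
})

#' @describeIn PermutationResult supra-threshold clusters with t-mass and
#'   permutation p-values.
#' @param x a PermutationResult.
#' @export
clusters <- function(x) x@clusters

#' @describeIn PermutationResult per-TR one-sample t statistics.
#' @export
clusterTstats <- function(x) x@tstats

setMethod("show", "PermutationResult", function(object) {
  cat("Cluster-mass permutation test (", object@nPermutations,
      " sign-flip permutations, cluster-forming alpha = ",
      object@thresholdAlpha, ")\n", sep = "")
  if (nrow(object@clusters) == 0L) {
    cat("  no supra-threshold clusters\n")
  } else {
    print(object@clusters, row.names = FALSE)
  }
})
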