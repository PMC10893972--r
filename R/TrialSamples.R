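#' TrialSamples: multivoxel patterns at a fixed delay offset
#'
#' A \linkS4class{SummarizedExperiment} with voxels as rows and trials as
#' columns. The \code{colData} carries the per-trial design: run index and
#' the orientation labels (target, distractor, and optionally probe start
#' and behavioural report). This is the object the periodic SVR decoder
#' consumes.
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("TrialSamples", contains = "SummarizedExperiment")

setValidity("TrialSamples", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("run", "target_deg") %in% names(cd)))
    msg <- c(msg, "colData must contain 'run' and 'target_deg'")
  if ("target_deg" %in% names(cd)) {
    th <- cd$target_deg
    if (any(th < 0 | th >= 180))
      msg <- c(msg, "target_deg must lie in [0, 180)")
  }
  if (!all(is.finite(SummarizedExperiment::assay(object))))
    msg <- c(msg, "sample values must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct TrialSamples
#'
#' @param samples numeric matrix, trials in rows and voxels in columns (the
#'   natural orientation in which decoding folds are built); stored
#'   transposed, voxels x trials, following the SummarizedExperiment
#'   convention of features in rows.
#' @param design data.frame with one row per trial; must contain columns
#'   \code{run} and \code{target_deg}, and may contain
#'   \code{distractor_deg}, \code{probe_start_deg}, \code{response_deg},
#'   \code{trial}, \code{subject}, \code{cue}.
#' @return a \linkS4class{TrialSamples}.
#' @export
TrialSamples <- function(samples, design) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (nrow(design) != nrow(samples))
    stop("design must have one row per trial (", nrow(samples), " trials, ",
         nrow(design), " design rows)")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = t(samples)),
    colData = S4Vectors::DataFrame(design)
  )
  new("TrialSamples", se)
}

#' @describeIn TrialSamples trial-by-voxel sample matrix.
#' @param x a TrialSamples object.
#' @export
sampleMatrix <- function(x) t(SummarizedExperiment::assay(x, "signal"))

#' @describeIn TrialSamples per-trial orientation labels (degrees) for a
#'   given label kind.
#' @param kind one of \code{"target"}, \code{"distractor"},
#'   \code{"probe_start"}, \code{"report"}.
#' @export
trialLabels <- function(x, kind = c("target", "distractor", "probe_start",
                                    "report")) {
  kind <- match.arg(kind)
  col <- switch(kind, target = "target_deg", distractor = "distractor_deg",
                probe_start = "probe_start_deg", report = "response_deg")
  cd <- SummarizedExperiment::colData(x)
  if (!col %in% names(cd))
    stop("label column '", col, "' not present for label kind '", kind, "'")
  as.numeric(cd[[col]])
}

#' @describeIn TrialSamples per-trial run indices.
#' @export
trialRuns <- function(x) as.integer(SummarizedExperiment::colData(x)$run)

#' @describeIn TrialSamples the full per-trial design table.
#' @export
trialDesign <- function(x) as.data.frame(SummarizedExperiment::colData(x))
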