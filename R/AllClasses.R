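#' @import methods
#' @importFrom stats coef cor.test dnorm optim qt rgamma rnorm runif sd
#'   spline t.test var
NULL

# Upper bound on von Mises precision accepted by the parameter container.
# Densities are evaluated with exponentially scaled Bessel functions, so
# values this large are numerically safe; they arise in degenerate
# simulations where responses should coincide with targets.
.kappaValidityMax <- 1e6

# Upper bound imposed during maximum-likelihood fitting; estimates at this
# boundary are flagged rather than trusted.
.kappaFitMax <- 700

#' VoxelSeries: multi-run voxel signal container
#'
#' Holds one real-valued matrix per run. In the \code{"trialwise"} layout
#' rows are trials (one multivoxel pattern per trial, as produced by the
#' generative simulator); in the \code{"timecourse"} layout rows are
#' timepoints (TRs) and \code{onsets} gives the first TR of each trial
#' within the run.
#'
#' @slot data list of numeric matrices, one per run; columns are voxels and
#'   all runs share the same voxel count.
#' @slot layout either \code{"trialwise"} or \code{"timecourse"}.
#' @slot onsets list of strictly increasing integer vectors, one per run:
#'   the row index at which each trial starts.
#' @slot trSeconds sampling interval of the series in seconds.
#' @export
setClass("VoxelSeries",
  representation(
    data = "list",
    layout = "character",
    onsets = "list",
    trSeconds = "numeric"
  )
)

setValidity("VoxelSeries", function(object) {
  msg <- character()
  if (!object@layout %in% c("trialwise", "timecourse"))
    msg <- c(msg, "layout must be 'trialwise' or 'timecourse'")
  if (length(object@data) < 1L)
    msg <- c(msg, "at least one run required")
  if (!all(vapply(object@data, is.matrix, logical(1))))
    msg <- c(msg, "each run must be a matrix")
  nv <- vapply(object@data, ncol, integer(1))
  if (length(unique(nv)) > 1L)
    msg <- c(msg, "all runs must have the same number of voxels")
  if (length(object@onsets) != length(object@data))
    msg <- c(msg, "one onset vector per run required")
  for (r in seq_along(object@data)) {
    on <- object@onsets[[r]]
    if (any(diff(on) <= 0))
      msg <- c(msg, sprintf("onsets must be strictly increasing (run %d)", r))
    if (any(on < 1L) || any(on > nrow(object@data[[r]])))
      msg <- c(msg, sprintf("onsets out of bounds (run %d)", r))
    if (object@layout == "trialwise" &&
        !identical(as.integer(on), seq_len(nrow(object@data[[r]]))))
      msg <- c(msg, sprintf("trialwise layout requires one row per trial (run %d)", r))
  }
  if (length(object@trSeconds) != 1L || object@trSeconds <= 0)
    msg <- c(msg, "trSeconds must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a VoxelSeries
#'
#' @param data list of numeric matrices (one per run, columns = voxels).
#' @param layout \code{"trialwise"} or \code{"timecourse"}.
#' @param onsets list of trial-onset row indices per run. Defaults to one
#'   row per trial for the trialwise layout.
#' @param trSeconds sampling interval in seconds (default 0.8, the
#'   acquisition TR of the experiment this package models).
#' @return a \linkS4class{VoxelSeries}.
#' @export
VoxelSeries <- function(data, layout = c("trialwise", "timecourse"),
                        onsets = NULL, trSeconds = 0.8) {
  layout <- match.arg(layout)
  data <- lapply(data, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  if (is.null(onsets)) {
    if (layout != "trialwise")
      stop("onsets must be supplied for the timecourse layout")
    onsets <- lapply(data, function(m) seq_len(nrow(m)))
  }
  onsets <- lapply(onsets, as.integer)
  new("VoxelSeries", data = data, layout = layout, onsets = onsets,
      trSeconds = trSeconds)
}

#' VMMMParams: von Mises mixture model parameters
#'
#' Parameters of the three-component model of delayed-estimation reports:
#' on each trial the observer either detects the target (von Mises response
#' error with precision kappa1 around the target plus a shared bias mu),
#' makes a swap error (same around the distractor, precision kappa2), or
#' guesses (uniform error on [-90, 90) degrees).
#'
#' @slot r numeric length-3 mixture weights (detection, swap, guess),
#'   summing to 1.
#' @slot kappa numeric length-2 nonnegative precisions (detection, swap).
#' @slot mu response bias in degrees, in [-90, 90).
#' @export
setClass("VMMMParams",
  representation(r = "numeric", kappa = "numeric", mu = "numeric")
)

setValidity("VMMMParams", function(object) {
  msg <- character()
  if (length(object@r) != 3L || any(object@r < 0))
    msg <- c(msg, "r must be three nonnegative mixture weights")
  if (abs(sum(object@r) - 1) > 1e-9)
    msg <- c(msg, "mixture weights must sum to 1 (tolerance 1e-9)")
  if (length(object@kappa) != 2L || any(object@kappa < 0) ||
      any(object@kappa > .kappaValidityMax))
    msg <- c(msg, sprintf("kappa must be two precisions in [0, %g]", .kappaValidityMax))
  if (length(object@mu) != 1L || object@mu < -90 || object@mu >= 90)
    msg <- c(msg, "mu must be a single bias in [-90, 90) degrees")
  if (length(msg)) msg else TRUE
})

#' Construct VMMMParams
#'
#' @param r1,r2,r3 mixture probabilities for detection, swap and guess.
#' @param kappa1,kappa2 von Mises precisions for detection and swap.
#' @param mu response bias in degrees in [-90, 90).
#' @return a \linkS4class{VMMMParams}.
#' @export
#' @examples
#' VMMMParams(0.947, 0.028, 0.025, kappa1 = 5.673, mu = -0.889)
VMMMParams <- function(r1, r2, r3, kappa1, kappa2 = 0, mu = 0) {
  new("VMMMParams", r = c(r1, r2, r3), kappa = c(kappa1, kappa2), mu = mu)
}

#' VMMMFit: fitted von Mises mixture model
#'
#' @slot params the maximum-likelihood \linkS4class{VMMMParams}.
#' @slot logLik final log-likelihood.
#' @slot converged logical, optimizer convergence of the best restart.
#' @slot boundary logical, TRUE when a precision estimate sits at the
#'   fitting bound (degenerate, e.g. error-free responses).
#' @slot nRestarts number of multistarts used.
#' @export
setClass("VMMMFit",
  representation(params = "VMMMParams", logLik = "numeric",
                 converged = "logical", boundary = "logical",
                 nRestarts = "integer")
)

#' ReconstructionTimecourse: time-resolved decoded orientations
#'
#' @slot predicted matrix [TR x trial] of decoded orientations in degrees.
#' @slot truth numeric per-trial true orientation for the decoded label.
#' @slot runs integer run index per trial.
#' @slot labelKind which label was decoded ("target", "distractor",
#'   "probe_start" or "report").
#' @slot bfcaByTR numeric per-TR balanced feature-continuous accuracy (%).
#' @slot subject subject identifier.
#' @export
setClass("ReconstructionTimecourse",
  representation(predicted = "matrix", truth = "numeric", runs = "integer",
                 labelKind = "character", bfcaByTR = "numeric",
                 subject = "character")
)

setValidity("ReconstructionTimecourse", function(object) {
  msg <- character()
  if (ncol(object@predicted) != length(object@truth))
    msg <- c(msg, "one predicted column per trial required")
  if (length(object@bfcaByTR) != nrow(object@predicted))
    msg <- c(msg, "one BFCA value per TR required")
  p <- object@predicted
  if (any(p < 0 | p >= 180, na.rm = TRUE))
    msg <- c(msg, "predictions must lie in [0, 180)")
  if (length(msg)) msg else TRUE
})

#' PermutationResult: cluster-mass permutation test outcome
#'
#' @slot clusters data.frame with columns tr_start, tr_end, t_mass,
#'   p_cluster; non-overlapping, sorted by tr_start.
#' @slot tstats per-TR one-sample t statistics against chance.
#' @slot nPermutations number of sign-flip permutations.
#' @slot thresholdAlpha one-tailed cluster-forming alpha.
#' @slot seed RNG seed used for the permutation draws.
#' @export
setClass("PermutationResult",
  representation(clusters = "data.frame", tstats = "numeric",
                 nPermutations = "integer", thresholdAlpha = "numeric",
                 seed = "integer")
)

setValidity("PermutationResult", function(object) {
  msg <- character()
  cl <- object@clusters
  need <- c("tr_start", "tr_end", "t_mass", "p_cluster")
  if (!all(need %in% names(cl)))
    msg <- c(msg, "clusters must have tr_start, tr_end, t_mass, p_cluster")
  if (nrow(cl)) {
    if (any(cl$p_cluster <= 0 | cl$p_cluster > 1))
      msg <- c(msg, "cluster p-values must lie in (0, 1]")
    if (is.unsorted(cl$tr_start, strictly = TRUE))
      msg <- c(msg, "clusters must be sorted by tr_start")
    if (nrow(cl) > 1L && any(cl$tr_start[-1L] <= cl$tr_end[-nrow(cl)]))
      msg <- c(msg, "clusters must not overlap")
  }
  if (length(msg)) msg else TRUE
})
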