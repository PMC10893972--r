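#' Generate a counterbalanced orientation working-memory trial design
#'
#' Builds the delayed-estimation design used throughout the package: per
#' run, 40 target orientations equally spaced by 180/40 = 4.5 degrees and
#' shifted off the cardinal axes by 1.125 degrees (so targets run from
#' 1.125 to 176.625), plus 40 distractor orientations offset by half a step
#' (2.25 degrees; 3.375 to 178.875). Each target and each distractor
#' appears exactly once per run, in independently randomized order, so the
#' sets are counterbalanced across runs. The retro-cue (1 = first grating
#' is the target, 2 = second) is drawn uniformly. A random probe start
#' orientation is drawn uniformly on [0, 180) per trial.
#'
#' @param nRuns number of runs (8 in the experiment; 8 runs x 40 trials =
#'   320 trials).
#' @param seed integer RNG seed; \code{NULL} leaves the RNG state alone.
#' @param subject subject identifier stored in the table.
#' @param orientations \code{"discrete"} for the 40-level counterbalanced
#'   set; \code{"continuous"} draws each target uniformly on [0, 180)
#'   (the convention of the pure simulation study) with distractors offset
#'   by 2.25.
#' @return data.frame with columns subject, run, trial, target_deg,
#'   distractor_deg, cue, probe_start_deg.
#' @export
#' @examples
#' d <- generateDesign(1, seed = 1)
#' range(d$target_deg)  # 1.125 .. 176.625
generateDesign <- function(nRuns = 8L, seed = NULL, subject = "sim01",
                           orientations = c("discrete", "continuous")) {
  orientations <- match.arg(orientations)
  stopifnot(nRuns >= 1L)
  if (!is.null(seed)) set.seed(seed)
  nTrials <- 40L
  targets <- 1.125 + 4.5 * (0:39)
  out <- lapply(seq_len(nRuns), function(r) {
    if (orientations == "discrete") {
      tg <- sample(targets)
      ds <- sample(wrap180(targets + 2.25))
    } else {
      tg <- runif(nTrials, 0, 180)
      ds <- wrap180(tg + 2.25)
    }
    data.frame(
      subject = subject, run = r, trial = seq_len(nTrials),
      target_deg = tg, distractor_deg = ds,
      cue = sample(1:2, nTrials, replace = TRUE),
      probe_start_deg = runif(nTrials, 0, 180)
    )
  })
  do.call(rbind, out)
}

#' Periodic (exp-sine-squared) covariance kernel
#'
#' Covariance between two points of a voxel's orientation tuning profile:
#' \code{exp(-2 sin^2((xm - xn) / 2) / sigma^2)}. The kernel is symmetric,
#' 2*pi-periodic in the lag, equals 1 at zero lag, and its length-scale
#' sigma is the voxel's tuning smoothness.
#'
#' @param xm,xn positions on the tuning grid in radians (vectorized).
#' @param sigma positive smoothness parameter.
#' @return covariance values in (0, 1].
#' @export
#' @examples
#' periodicKernel(0, pi, 1)  # exp(-2)
periodicKernel <- function(xm, xn, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  exp(-2 * sin((xm - xn) / 2)^2 / sigma^2)
}

#' Sample smooth periodic orientation tuning profiles
#'
#' Each voxel's tuning profile over a grid of \code{gridSize} equally
#' spaced orientations on [0, 2*pi) is drawn from a zero-mean multivariate
#' normal with the periodic covariance kernel, using a per-voxel smoothness
#' sigma_i drawn from a gamma distribution (shape 2, scale 2 by default;
#' the scale parameterization is deliberate and exposed). A small diagonal
#' jitter keeps the covariance factorization numerically positive definite.
#'
#' @param nVoxels number of voxels.
#' @param gridSize number of grid points p (default 180, giving at most 1
#'   degree of quantization when trial orientations are mapped onto the
#'   grid).
#' @param seed integer RNG seed; \code{NULL} leaves the RNG state alone.
#' @param shape,scale gamma parameters for the smoothness draw.
#' @param jitter diagonal stabilizer added before Cholesky factorization.
#' @return list of profiles; each has \code{grid} (radians),
#'   \code{values} (tuning curve, length \code{gridSize}) and
#'   \code{smoothness} (sigma_i).
#' @export
sampleTuningProfiles <- function(nVoxels, gridSize = 180L, seed = NULL,
                                 shape = 2, scale = 2, jitter = 1e-6) {
  stopifnot(nVoxels >= 1L, gridSize >= 2L)
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(0, 2 * pi, length.out = gridSize + 1L)[seq_len(gridSize)]
  sigmas <- rgamma(nVoxels, shape = shape, scale = scale)
  # group voxels by smoothness-identical kernels is pointless (all sigmas
  # differ); factorize per voxel.
  lapply(seq_len(nVoxels), function(i) {
    K <- periodicKernel(outer(grid, rep(1, gridSize)),
                        outer(rep(1, gridSize), grid), sigmas[i])
    diag(K) <- diag(K) + jitter
    L <- tryCatch(chol(K), error = function(e)
      stop("covariance not positive definite after jitter for sigma = ",
           signif(sigmas[i], 4), ": ", conditionMessage(e)))
    z <- drop(crossprod(L, rnorm(gridSize)))
    list(grid = grid, values = z, smoothness = sigmas[i])
  })
}

# Map orientations in [0, 180) to nearest-grid-point indices of a p-point
# grid on [0, 2*pi): theta -> 2*pi*theta/180, then nearest point.
.gridIndex <- function(thetaDeg, gridSize) {
  if (any(thetaDeg < 0 | thetaDeg >= 180))
    stop("orientations must lie in [0, 180)")
  x <- 2 * pi * thetaDeg / 180
  step <- 2 * pi / gridSize
  (round(x / step) %% gridSize) + 1L
}

#' Simulate trialwise voxel responses
#'
#' The measured signal of voxel i on trial j is \code{y_ij = r_ij * s +
#' e_ij}: the voxel's tuning value at the trial's orientation (nearest
#' point of the simulation grid), scaled by the signal-to-noise factor s,
#' plus standard-normal noise independent across trials, voxels and runs.
#'
#' @param profiles tuning profiles from \code{\link{sampleTuningProfiles}}.
#' @param design trial table from \code{\link{generateDesign}}.
#' @param snr scaling factor s >= 0 (0 = pure noise).
#' @param seed integer RNG seed for the noise; \code{NULL} leaves the RNG
#'   state alone.
#' @param drivenBy which design orientation drives the voxels (default the
#'   target, i.e. the memorized stimulus).
#' @return a trialwise \linkS4class{VoxelSeries} (one row per trial).
#' @export
simulateVoxelResponses <- function(profiles, design, snr, seed = NULL,
                                   drivenBy = c("target", "distractor")) {
  stopifnot(snr >= 0)
  drivenBy <- match.arg(drivenBy)
  if (!is.null(seed)) set.seed(seed)
  col <- if (drivenBy == "target") "target_deg" else "distractor_deg"
  gridSize <- length(profiles[[1L]]$grid)
  tuning <- vapply(profiles, `[[`, numeric(gridSize), "values")  # grid x voxel
  runs <- sort(unique(design$run))
  data <- lapply(runs, function(r) {
    d <- design[design$run == r, , drop = FALSE]
    idx <- .gridIndex(d[[col]], gridSize)
    resp <- tuning[idx, , drop = FALSE] * snr
    resp + matrix(rnorm(length(resp)), nrow(resp), ncol(resp))
  })
  VoxelSeries(data, layout = "trialwise")
}

#' Expand a trialwise simulation into a TR-resolved timecourse
#'
#' Places each trial's multivoxel pattern into a contiguous window of TRs
#' (the "active" TRs, e.g. the delay period) and fills the remaining TRs
#' of the trial with fresh unit-variance noise around zero, so that the
#' time-resolved decoder can be exercised: decodable information exists
#' only inside the active window. Trial onsets are populated accordingly.
#'
#' @param trialwise a trialwise \linkS4class{VoxelSeries}.
#' @param trsPerTrial number of TRs allocated to each trial.
#' @param activeWindow integer vector of TR indices within the trial
#'   (1-based, inclusive) that carry the trial pattern.
#' @param seed integer RNG seed for the background noise.
#' @return a timecourse-layout \linkS4class{VoxelSeries}.
#' @export
expandToTimecourse <- function(trialwise, trsPerTrial, activeWindow,
                               seed = NULL) {
  stopifnot(seriesLayout(trialwise) == "trialwise")
  activeWindow <- as.integer(activeWindow)
  if (length(activeWindow) == 0L)
    stop("activeWindow must contain at least one TR")
  if (any(activeWindow < 1L) || any(activeWindow > trsPerTrial))
    stop("activeWindow must lie within [1, trsPerTrial]")
  if (!is.null(seed)) set.seed(seed)
  data <- lapply(voxelData(trialwise), function(m) {
    nT <- nrow(m); nV <- ncol(m)
    out <- matrix(rnorm(nT * trsPerTrial * nV), nT * trsPerTrial, nV)
    for (j in seq_len(nT)) {
      rows <- (j - 1L) * trsPerTrial + activeWindow
      out[rows, ] <- matrix(m[j, ], length(rows), nV, byrow = TRUE)
    }
    out
  })
  onsets <- lapply(voxelData(trialwise), function(m)
    (seq_len(nrow(m)) - 1L) * trsPerTrial + 1L)
  VoxelSeries(data, layout = "timecourse", onsets = onsets,
              trSeconds = trSeconds(trialwise))
}

# von Mises sampler (Best & Fisher 1979 envelope-rejection), mean 0,
# values in (-pi, pi]. Used on the doubled-angle scale.
rvonmises <- function(n, kappa) {
  if (kappa == 0) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nf <- sum(keep)
    if (nf > 0L) {
      out[got + seq_len(nf)] <- sign(u3[keep] - 0.5) * acos(pmin(1, pmax(-1, f[keep])))
      got <- got + nf
    }
  }
  out
}

#' Simulate delayed-estimation reports from the mixture model
#'
#' Per trial, an outcome is drawn with probabilities (r1, r2, r3):
#' detections respond around the target plus bias with von Mises precision
#' kappa1, swap errors respond around the distractor with kappa2 (same
#' bias), guesses have errors uniform on [-90, 90). Errors are drawn on
#' the doubled-angle scale and mapped back to degrees; responses are
#' reduced into [0, 180).
#'
#' @param design trial table from \code{\link{generateDesign}}.
#' @param params a \linkS4class{VMMMParams}.
#' @param seed integer RNG seed.
#' @return the design with added columns \code{response_deg} and
#'   \code{outcome} (1 detection, 2 swap, 3 guess).
#' @export
simulateBehavior <- function(design, params, seed = NULL) {
  stopifnot(is(params, "VMMMParams"))
  validObject(params)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(design)
  comp <- sample.int(3L, n, replace = TRUE, prob = params@r)
  errDeg <- numeric(n)
  for (k in 1:2) {
    idx <- comp == k
    if (any(idx))
      errDeg[idx] <- rvonmises(sum(idx), params@kappa[k]) * 90 / pi
  }
  idx <- comp == 3L
  if (any(idx)) errDeg[idx] <- runif(sum(idx), -90, 90)
  centre <- ifelse(comp == 2L, design$distractor_deg, design$target_deg)
  centre[comp == 3L] <- design$target_deg[comp == 3L]
  design$response_deg <- wrap180(centre + params@mu + errDeg)
  design$outcome <- comp
  design
}

#' Simulate a complete trialwise dataset
#'
#' Convenience wrapper: design, tuning profiles and voxel responses in one
#' call with sub-seeds derived per stage from one master seed, so every
#' stage is independently reproducible.
#'
#' @param nRuns,nVoxels,snr,gridSize simulation settings; the defaults
#'   reproduce the simulation-study conditions (8 runs x 40 trials, 250
#'   voxels).
#' @param seed master integer seed.
#' @param orientations passed to \code{\link{generateDesign}}.
#' @return list with \code{design} and trialwise \code{series}.
#' @export
simulateVoxelDataset <- function(nRuns = 8L, nVoxels = 250L, snr = 0.5,
                                 gridSize = 180L, seed = 1L,
                                 orientations = "discrete") {
  design <- generateDesign(nRuns, seed = deriveSeed(seed, "design"),
                           orientations = orientations)
  profiles <- sampleTuningProfiles(nVoxels, gridSize,
                                   seed = deriveSeed(seed, "tuning"))
  series <- simulateVoxelResponses(profiles, design, snr,
                                   seed = deriveSeed(seed, "noise"))
  list(design = design, series = series)
}

#' Read/write trial and response tables as TSV
#'
#' @param design a design/response data.frame.
#' @param path file path.
#' @return \code{readDesignTsv} returns the data.frame.
#' @export
writeDesignTsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeDesignTsv
#' @export
readDesignTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write/read a VoxelSeries as flat binary plus JSON sidecar
#'
#' The signal is stored as 64-bit floats in run-major, row-major (timepoint
#' or trial), voxel-minor order; the sidecar records shape, layout, onsets
#' and the sampling interval.
#'
#' @param series a \linkS4class{VoxelSeries}.
#' @param path path of the binary file; the sidecar is written to
#'   \code{paste0(path, ".json")}.
#' @return \code{readVoxelSeries} returns the \linkS4class{VoxelSeries}.
#' @export
writeVoxelSeries <- function(series, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (m in voxelData(series)) writeBin(as.vector(t(m)), con, size = 8)
  meta <- list(
    shape = lapply(voxelData(series), dim),
    layout = seriesLayout(series),
    onsets = trialOnsets(series),
    tr_seconds = trSeconds(series)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeVoxelSeries
#' @export
readVoxelSeries <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  shapes <- if (is.matrix(meta$shape)) {
    lapply(seq_len(nrow(meta$shape)), function(i) meta$shape[i, ])
  } else meta$shape
  data <- lapply(shapes, function(dm) {
    v <- readBin(con, "double", n = prod(dm), size = 8)
    matrix(v, dm[1], dm[2], byrow = TRUE)
  })
  onsets <- meta$onsets
  if (is.matrix(onsets))
    onsets <- lapply(seq_len(nrow(onsets)), function(i) onsets[i, ])
  VoxelSeries(data, layout = meta$layout, onsets = onsets,
              trSeconds = meta$tr_seconds)
}
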