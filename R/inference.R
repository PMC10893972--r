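#' Cluster-mass permutation test of above-chance decoding over time
#'
#' Tests at which TRs a group decoding timecourse exceeds chance while
#' controlling family-wise error over the (autocorrelated) time axis.
#' Per TR, a one-sample t statistic of (accuracy - chance) is computed
#' across subjects; contiguous TRs whose t exceeds the one-tailed
#' cluster-forming threshold (alpha on the t distribution, above-chance
#' direction only) form clusters scored by their t-mass (sum of t
#' values). The null distribution of the maximum cluster mass is obtained
#' by randomly sign-flipping each subject's chance-centred timecourse;
#' each observed cluster gets p = (1 + #permutations with max mass >=
#' observed) / (1 + nPerm).
#'
#' @param accuracy numeric matrix, subjects x TRs, of accuracies in
#'   percent; at least 5 subjects.
#' @param chance chance level subtracted before testing (default 50).
#' @param nPerm number of sign-flip permutations (>= 100; default 10000).
#' @param alpha one-tailed cluster-forming alpha (default 0.05).
#' @param seed integer RNG seed for the sign flips.
#' @return a \linkS4class{PermutationResult}.
#' @export
clusterPermutation <- function(accuracy, chance = 50, nPerm = 10000L,
                               alpha = 0.05, seed = NULL) {
  accuracy <- as.matrix(accuracy)
  S <- nrow(accuracy); TT <- ncol(accuracy)
  if (S < 5L) stop("at least 5 subjects required")
  nPerm <- as.integer(nPerm)
  if (nPerm < 100L) stop("at least 100 permutations required")
  if (!is.null(seed)) set.seed(seed)

  d <- accuracy - chance
  sds <- apply(d, 2L, sd)
  zero <- sds == 0
  if (any(zero))
    warning(sum(zero), " TR(s) with zero variance excluded from clustering")
  tstat <- colMeans(d) / (sds / sqrt(S))
  tstat[zero] <- NA_real_
  thr <- qt(1 - alpha, df = S - 1L)

  findClusters <- function(tv) {
    supra <- !is.na(tv) & tv >= thr
    if (!any(supra)) return(NULL)
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    data.frame(tr_start = starts[keep], tr_end = ends[keep],
               t_mass = vapply(keep, function(k)
                 sum(tv[starts[k]:ends[k]]), numeric(1)))
  }
  obs <- findClusters(tstat)

  # vectorized sign-flip null: flipped per-subject signs leave each d_i^2
  # unchanged, so only the mean changes per permutation
  signs <- matrix(sample(c(-1, 1), nPerm * S, replace = TRUE), nPerm, S)
  m <- signs %*% d / S
  sq <- matrix(colSums(d^2), nPerm, TT, byrow = TRUE)
  vp <- (sq - S * m^2) / (S - 1L)
  vp[vp < 0] <- 0
  tp <- m / sqrt(vp / S)
  tp[, zero] <- NA_real_
  maxMass <- apply(tp, 1L, function(tv) {
    cl <- findClusters(tv)
    if (is.null(cl)) 0 else max(cl$t_mass)
  })

  if (is.null(obs)) {
    cl <- data.frame(tr_start = integer(), tr_end = integer(),
                     t_mass = numeric(), p_cluster = numeric())
  } else {
    obs$p_cluster <- vapply(obs$t_mass, function(msx)
      (1 + sum(maxMass >= msx)) / (1 + nPerm), numeric(1))
    cl <- obs
  }
  new("PermutationResult", clusters = cl, tstats = tstat,
      nPermutations = nPerm, thresholdAlpha = alpha,
      seed = as.integer(seed %||% NA_integer_))
}

#' Two-tailed two-sample t test (pooled variance)
#'
#' @param a,b per-subject scalar outcomes for the two groups (each of
#'   size >= 2).
#' @return list with \code{t}, \code{df} and two-tailed \code{p}.
#' @export
#' @examples
#' groupCompare(c(1, 2, 3), c(4, 5, 6))
groupCompare <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 subjects")
  if (var(a) == 0 && var(b) == 0 && mean(a) == mean(b))
    return(list(t = 0, df = length(a) + length(b) - 2L, p = 1))
  if (var(a) == 0 && var(b) == 0)
    stop("zero pooled variance")
  tt <- t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Pearson correlation with two-tailed p value
#'
#' @param x,y per-subject scalars, n >= 3, nonzero variance.
#' @return list with \code{r} and \code{p}.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least 3 subjects required")
  if (var(x) == 0 || var(y) == 0) stop("zero variance")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = unname(ct$p.value))
}

#' Nested across-subject assignment of smoothing width and voxel count
#'
#' Leave-one-subject-out hyperparameter selection: for each subject, the
#' accuracy of every (FWHM, voxel count) grid cell is averaged over the
#' delay-period TR window and over all other subjects, and the argmax
#' cell is assigned to the held-out subject. The subject's own accuracies
#' are never consulted. Exact ties go to the smaller FWHM, then the
#' smaller voxel count.
#'
#' @param grid 4-dimensional accuracy array indexed
#'   [subject, fwhm, voxelCount, tr].
#' @param trWindow integer TR indices (1-based) to average over.
#' @param fwhmValues,voxelCounts the grid axis values (defaults: FWHM 0
#'   to 90 by 10 degrees; 250 to 2500 voxels by 250).
#' @return data.frame with one row per subject: \code{subject},
#'   \code{fwhm}, \code{n_voxels}.
#' @export
nestedGridAssign <- function(grid, trWindow,
                             fwhmValues = seq(0, 90, by = 10),
                             voxelCounts = seq(250, 2500, by = 250)) {
  stopifnot(length(dim(grid)) == 4L)
  if (dim(grid)[2L] != length(fwhmValues) ||
      dim(grid)[3L] != length(voxelCounts))
    stop("grid dimensions do not match the fwhm/voxel axes")
  nSubj <- dim(grid)[1L]
  if (nSubj < 2L) stop("at least 2 subjects required")
  trWindow <- as.integer(trWindow)
  if (any(trWindow < 1L) || any(trWindow > dim(grid)[4L]))
    stop("TR window outside the grid")
  if (any(!is.finite(grid[, , , trWindow])))
    stop("incomplete grid: non-finite accuracy in the TR window")
  out <- data.frame(subject = seq_len(nSubj), fwhm = NA_real_,
                    n_voxels = NA_real_)
  for (s in seq_len(nSubj)) {
    sub <- grid[-s, , , trWindow, drop = FALSE]
    cell <- apply(sub, c(2L, 3L), mean)
    best <- max(cell)
    hit <- which(cell == best, arr.ind = TRUE)
    # ties: smallest FWHM first, then smallest voxel count
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    out$fwhm[s] <- fwhmValues[hit[1L, 1L]]
    out$n_voxels[s] <- voxelCounts[hit[1L, 2L]]
  }
  out
}

#' Write group statistics as TSV
#'
#' @param stats data.frame of comparisons (columns comparison, t, df, p
#'   or r, p).
#' @param path output path.
#' @export
writeGroupStatsTsv <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a permutation result as JSON
#'
#' @param res a \linkS4class{PermutationResult}.
#' @param path output path.
#' @export
writePermutationJson <- function(res, path) {
  jsonlite::write_json(list(
    clusters = clusters(res),
    n_permutations = res@nPermutations,
    threshold_alpha = res@thresholdAlpha,
    seed = res@seed
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
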