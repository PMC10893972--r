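#' Feature-continuous accuracy (FCA)
#'
#' Linear rescaling of the absolute circular deviation between true and
#' reconstructed orientation (0 to 90 degrees under 180-degree
#' periodicity) onto a 0-100% accuracy scale:
#' FCA = (90 - |theta - theta-hat|_circ) / 90 * 100. 100% is perfect
#' reconstruction, 50% (a 45-degree deviation) is chance for circular
#' orientation data, 0% is an orthogonal reconstruction.
#'
#' @param true,predicted orientations in degrees, [0, 180) (vectorized).
#' @return accuracies in [0, 100].
#' @export
#' @examples
#' fca(10, 10)    # 100
#' fca(0, 45)     # 50, chance level
#' fca(0, 90)     # 0, orthogonal
fca <- function(true, predicted) {
  if (any(c(true, predicted) < 0 | c(true, predicted) >= 180))
    stop("orientations must lie in [0, 180)")
  (90 - abs(circDiff180(true, predicted))) / 90 * 100
}

#' Balanced feature-continuous accuracy (BFCA)
#'
#' Integral of the trialwise FCA over the orientation space,
#' BFCA = (1/180) * int_0^180 FCA d(theta), evaluated by trapezoidal
#' integration across the trials sorted by true orientation. The
#' integration reweights trials by how sparsely their true label region
#' is sampled, so densely sampled label regions cannot dominate the
#' score - the continuous analogue of balanced accuracy.
#'
#' Two conventions close the quadrature: FCA values of trials sharing an
#' identical true label are averaged first (zero-width trapezoids would
#' otherwise make the result order-dependent), and the first sorted trial
#' is re-appended at its label + 180 degrees so the trapezoids cover one
#' full period (this respects periodicity and makes constant FCA
#' integrate exactly to itself).
#'
#' @param true,predicted orientations in degrees, [0, 180); at least two
#'   trials.
#' @return scalar balanced accuracy in percent.
#' @export
bfca <- function(true, predicted) {
  if (length(true) < 2L) stop("at least two trials required")
  if (length(true) != length(predicted))
    stop("true and predicted must have equal length")
  f <- fca(true, predicted)
  fm <- vapply(split(f, true), mean, numeric(1))
  u <- as.numeric(names(fm))
  o <- order(u)
  u <- u[o]; fm <- fm[o]
  u <- c(u, u[1L] + 180)
  fm <- c(fm, fm[1L])
  sum(diff(u) * (fm[-1L] + fm[-length(fm)]) / 2) / 180
}

#' Mean balanced accuracy over a TR window
#'
#' Averages the per-TR BFCA of a reconstruction timecourse over a window
#' of TRs (1-based, counted from delay onset). The delay-period window of
#' the experiment this package models is TRs 6-15 (10 TRs), chosen to
#' exclude the hemodynamic spill-over of stimulus and probe responses.
#'
#' @param timecourse a \linkS4class{ReconstructionTimecourse}.
#' @param trWindow integer vector of TR indices, e.g. \code{6:15}.
#' @return scalar mean accuracy in percent.
#' @export
meanWindowAccuracy <- function(timecourse, trWindow = 6:15) {
  trWindow <- as.integer(trWindow)
  if (length(trWindow) == 0L) stop("empty TR window")
  bf <- bfcaTimecourse(timecourse)
  if (any(trWindow < 1L) || any(trWindow > length(bf)))
    stop("TR window outside the decoded timecourse")
  mean(bf[trWindow])
}

#' Write per-TR accuracy as TSV
#'
#' @param tc a \linkS4class{ReconstructionTimecourse}.
#' @param path output path.
#' @export
writeAccuracyTsv <- function(tc, path) {
  df <- data.frame(subject = tc@subject,
                   tr = seq_along(bfcaTimecourse(tc)),
                   label_kind = labelKind(tc),
                   bfca_percent = bfcaTimecourse(tc))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
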