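#' von Mises mixture density of a delayed-estimation report
#'
#' Evaluates the three-component mixture: a von Mises term around the
#' target (precision kappa1), a von Mises term around the distractor
#' (precision kappa2) and a uniform guessing term. Angular differences are
#' taken in the 180-degree-periodic orientation space and mapped onto the
#' doubled-angle scale (degrees times pi/90), where the von Mises lives on
#' the full circle; the shared response bias mu (degrees) is subtracted in
#' both von Mises terms after the same scaling. The density is with
#' respect to the doubled-angle radian measure, so it integrates to 1 over
#' one period. The signed difference is taken response-minus-centre, so
#' the fitted bias estimates the mean signed response error: reports
#' generated as centre + mu + error are recovered with bias mu.
#'
#' Bessel normalizers use exponential scaling, so very large precisions
#' (degenerate, error-free data) evaluate without overflow.
#'
#' @param response,target,distractor orientations in degrees, [0, 180)
#'   (vectorized, recycled).
#' @param params a \linkS4class{VMMMParams}.
#' @return nonnegative density values.
#' @export
#' @examples
#' p <- VMMMParams(0, 0, 1, kappa1 = 0)
#' vmmmDensity(10, 50, 100, p)  # 1 / (2*pi), pure guessing
vmmmDensity <- function(response, target, distractor, params) {
  stopifnot(is(params, "VMMMParams"))
  validObject(params)
  muRad <- params@mu * pi / 90
  dens <- params@r[3] / (2 * pi)
  centres <- list(target, distractor)
  for (k in 1:2) {
    if (params@r[k] == 0) next
    kap <- params@kappa[k]
    dphi <- circDiff180(response, centres[[k]]) * pi / 90
    # exp(k cos x) / (2 pi I0(k)) == exp(k (cos x - 1)) / (2 pi e^-k I0(k))
    dens <- dens + params@r[k] * exp(kap * (cos(dphi - muRad) - 1)) /
      (2 * pi * besselI(kap, 0, expon.scaled = TRUE))
  }
  dens
}

#' Log-likelihood of a behavioural dataset under the mixture model
#'
#' Sum of per-trial log densities; densities are floored at 1e-300 so the
#' result is finite even for parameters that assign (numerically) zero
#' probability to an observed response.
#'
#' @param data data.frame with columns \code{target_deg},
#'   \code{distractor_deg} and \code{response_deg}, one row per trial.
#' @param params a \linkS4class{VMMMParams}.
#' @return scalar log-likelihood.
#' @export
vmmmLogLik <- function(data, params) {
  if (nrow(data) == 0L) stop("empty behavioural dataset")
  d <- vmmmDensity(data$response_deg, data$target_deg,
                   data$distractor_deg, params)
  sum(log(pmax(d, 1e-300)))
}

# Unconstrained parameter transform used by the optimizer:
# r = softmax(a1, a2, 0); kappa = exp(logk) clamped to the fitting bound;
# mu = 90 * tanh(m). Raw values are clamped so extreme optimizer steps
# cannot leave the valid parameter region (tanh(15) keeps mu < 90).
.vmmmFromRaw <- function(raw) {
  raw <- pmin(pmax(raw, -500), 500)
  ea <- exp(c(raw[1], raw[2], 0) - max(raw[1], raw[2], 0))
  r <- ea / sum(ea)
  kap <- pmin(exp(raw[3:4]), .kappaFitMax)
  m <- min(max(raw[5], -15), 15)
  new("VMMMParams", r = r, kappa = kap, mu = 90 * tanh(m))
}

#' Fit the von Mises mixture model by maximum likelihood
#'
#' Constrained maximization of \code{\link{vmmmLogLik}} on an
#' unconstrained reparameterization (softmax for the mixture weights, log
#' for the precisions, tanh for the bias), run from multiple start points
#' to guard against local optima of the mixture likelihood. The precision
#' search is capped at 700; estimates at that bound are flagged as
#' boundary fits (they arise for error-free, degenerate data).
#'
#' A von Mises component whose fitted precision is at most 0.1 is
#' observationally equivalent to the uniform guessing component (the
#' mixture is not identifiable along that ridge), so its mass is
#' reported as guessing and its precision set to 0: the canonical
#' decomposition.
#'
#' @param data data.frame with \code{target_deg}, \code{distractor_deg},
#'   \code{response_deg}.
#' @param nRestarts number of multistarts (first start is moment-based,
#'   the rest random).
#' @param seed integer RNG seed for the random starts.
#' @return a \linkS4class{VMMMFit}.
#' @export
fitVmmm <- function(data, nRestarts = 10L, seed = NULL) {
  if (nrow(data) == 0L) stop("empty behavioural dataset")
  if (nrow(data) < 40L)
    warning("fewer than 40 trials; mixture estimates may be unstable")
  if (!is.null(seed)) set.seed(seed)

  negll <- function(raw) {
    if (any(!is.finite(raw))) return(1e10)
    v <- -vmmmLogLik(data, .vmmmFromRaw(raw))
    if (!is.finite(v)) 1e10 else v
  }

  # moment-based first start: precision from the circular spread of
  # target-relative errors on the doubled-angle scale
  err <- circDiff180(data$response_deg, data$target_deg) * pi / 90
  R <- sqrt(mean(cos(err))^2 + mean(sin(err))^2)
  k0 <- if (R < 0.9) R * (2 - R^2) / (1 - R^2) else
    1 / (R^3 - 4 * R^2 + 3 * R)   # standard A1-inverse approximations
  k0 <- min(max(k0, 0.5), .kappaFitMax / 2)
  starts <- vector("list", nRestarts)
  starts[[1L]] <- c(2, -1, log(k0), log(k0), atanh(min(max(
    mean(err) * 90 / pi, -45), 45) / 90))
  if (nRestarts > 1L) {
    for (i in 2:nRestarts)
      starts[[i]] <- c(rnorm(2, 0, 2), runif(2, log(0.5), log(50)),
                       rnorm(1, 0, 0.05))
  }

  best <- NULL
  anyOk <- FALSE
  for (st in starts) {
    fit <- tryCatch(
      optim(st, negll, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    anyOk <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!anyOk) stop("optimizer failed on all restarts")

  params <- .vmmmFromRaw(best$par)
  # identifiability: a von Mises component with precision near 0 is
  # observationally equivalent to the uniform guessing component, so its
  # mass is reported as guessing (canonical decomposition)
  r <- params@r; kap <- params@kappa
  for (k in 1:2) {
    if (kap[k] <= 0.1 && r[k] > 0) {
      r[3] <- r[3] + r[k]
      r[k] <- 0
      kap[k] <- 0
    }
  }
  params <- new("VMMMParams", r = r, kappa = kap, mu = params@mu)
  boundary <- any(params@kappa >= .kappaFitMax * (1 - 1e-6))
  new("VMMMFit", params = params, logLik = vmmmLogLik(data, params),
      converged = best$convergence == 0L, boundary = boundary,
      nRestarts = as.integer(nRestarts))
}

#' Write a fitted mixture model as JSON
#'
#' @param fit a \linkS4class{VMMMFit}.
#' @param path output path.
#' @export
writeVmmmJson <- function(fit, path) {
  p <- fittedParams(fit)
  jsonlite::write_json(list(
    r1 = p@r[1], r2 = p@r[2], r3 = p@r[3],
    kappa1 = p@kappa[1], kappa2 = p@kappa[2], mu_deg = p@mu,
    loglik = fitLogLik(fit), converged = fit@converged,
    boundary = fit@boundary
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
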