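#' Reduce angles into the orientation space [0, 180)
#'
#' Grating orientations are 180-degree periodic: a grating at theta and at
#' theta + 180 is the same stimulus. All user-facing angles in this package
#' live in [0, 180).
#'
#' @param theta numeric vector of angles in degrees.
#' @return numeric vector in [0, 180).
#' @export
#' @examples
#' wrap180(c(-10, 0, 90, 180, 271.5))
wrap180 <- function(theta) {
  out <- theta %% 180
  # guard against 180 - eps rounding to exactly 180 under %%
  out[out >= 180] <- 0
  out
}

#' Signed circular difference of two orientations
#'
#' Returns the signed minimal difference a - b under 180-degree periodicity,
#' in [-90, 90). This is the circular-difference operator used both by the
#' behavioural mixture model and by the accuracy metrics.
#'
#' @param a,b numeric vectors of orientations in degrees (recycled).
#' @return signed differences in degrees, in [-90, 90).
#' @export
#' @examples
#' circDiff180(30, 30)   # 0
#' circDiff180(1, 179)   # 2: -178 is equivalent to +2 modulo 180
circDiff180 <- function(a, b) {
  d <- (a - b) %% 180
  d[d >= 90] <- d[d >= 90] - 180
  d
}

# Deterministic sub-seed derivation: one master seed per dataset, with
# independent sub-streams per named stage (and optional index) so that e.g.
# the tuning profiles do not shift when the number of behavioural draws
# changes. Kept strictly below 2^31 - 1.
deriveSeed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * (seq_along(utf8ToInt(as.character(stage))) %% 31 + 1))
  val <- (as.double(master) %% 1048573) * 2039 + h * 9176 + as.double(index) * 31
  as.integer(val %% 2147483629) + 1L
}

# Moving average with shrinking windows at the edges (no padding artifacts,
# output length equals input length).
movingAverage <- function(x, width) {
  n <- length(x)
  half <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
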