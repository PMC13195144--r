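#' Weighted energy distance between two one-dimensional samples
#'
#' The energy distance between distributions \eqn{P} and \eqn{Q} is
#' \deqn{\mathcal{E}(P,Q) = 2 E|X - Y| - E|X - X'| - E|Y - Y'|}
#' estimated here as the V-statistic on weighted empirical distributions
#' (weights normalized to probabilities). For scalar samples this equals
#' \eqn{2\int (F_P - F_Q)^2\,dt}, which is what this \eqn{O(n\log n)}
#' implementation computes from the pooled sorted sample; it agrees with the
#' \eqn{O(n^2)} double loop to numerical precision.
#'
#' @param x,y Numeric sample values (non-empty, finite).
#' @param wx,wy Optional positive weights (default: unit weights).
#' @return Non-negative scalar; 0 iff the weighted empirical distributions
#'   coincide.
#' @examples
#' energy_distance(0, 1)          # point masses at 0 and 1 -> 2
#' energy_distance(c(0, 2), c(1, 3))  # -> 1
#' @export
energy_distance <- function(x, y, wx = NULL, wy = NULL) {
  if (length(x) == 0L || length(y) == 0L) stop("samples must be non-empty")
  if (is.null(wx)) wx <- rep(1, length(x))
  if (is.null(wy)) wy <- rep(1, length(y))
  if (length(wx) != length(x) || length(wy) != length(y)) {
    stop("weights must match sample lengths")
  }
  if (any(wx <= 0) || any(wy <= 0)) stop("weights must be positive")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  wx <- wx / sum(wx)
  wy <- wy / sum(wy)
  # pooled step functions of both weighted CDFs
  t <- c(x, y)
  dF <- c(wx, numeric(length(y)))
  dG <- c(numeric(length(x)), wy)
  o <- order(t)
  t <- t[o]
  Fc <- cumsum(dF[o])
  Gc <- cumsum(dG[o])
  n <- length(t)
  if (n < 2L) return(0)
  dt <- t[-1L] - t[-n]
  2 * sum((Fc[-n] - Gc[-n])^2 * dt)
}

#' Mutual-information-corrected distance
#'
#' Scales a raw inter-organ distance down in proportion to the normalized
#' mutual information between the two organs' SUV fields:
#' \eqn{D^* = D\,(1 - \alpha\,\mathrm{MI})} with \eqn{\alpha \in [0, 1)}
#' (\eqn{\alpha = 0}: no correction). \eqn{\alpha = 1} is accepted only via
#' [build_connectome()]'s `allow_alpha_one` guard, which clips MI below 1.
#'
#' @param D Non-negative raw distance (vectorized).
#' @param MI Normalized mutual information in `[0, 1]` (vectorized).
#' @param alpha Correction strength in `[0, 1)` (or exactly 1 if
#'   `allow_alpha_one = TRUE` and `MI < 1`).
#' @param allow_alpha_one Accept `alpha = 1` (MI must then be strictly
#'   below 1).
#' @return Corrected distance(s) `D * (1 - alpha * MI)`, non-negative.
#' @export
corrected_distance <- function(D, MI, alpha, allow_alpha_one = FALSE) {
  if (length(alpha) != 1L || !is.finite(alpha)) stop("alpha must be a scalar")
  if (alpha < 0 || alpha > 1 || (alpha == 1 && !allow_alpha_one)) {
    stop("alpha must lie in [0, 1); alpha = 1 requires allow_alpha_one = TRUE")
  }
  if (any(D < 0)) stop("D must be >= 0")
  if (any(MI < 0 | MI > 1)) stop("MI must lie in [0, 1]")
  if (alpha == 1 && any(MI >= 1)) {
    stop("alpha = 1 requires MI strictly below 1 (clip MI first)")
  }
  D * (1 - alpha * MI)
}

#' Exponential similarity
#'
#' Maps a corrected distance to an adjacency weight in `(0, 1]`:
#' `exp(-d_star)`. Strictly decreasing, equal to 1 at zero distance.
#'
#' @param d_star Non-negative distance(s).
#' @return Similarity value(s) in `(0, 1]`.
#' @export
similarity <- function(d_star) {
  if (any(d_star < 0)) stop("distance must be >= 0")
  exp(-d_star)
}
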