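## Circular-statistics kernel used by every other module.
## Convention: all user-facing angles are degrees; positive rotation is
## counterclockwise. Wrapped differences live in (-180, 180], with the
## boundary mapped to +180.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into (-180, 180] degrees
#'
#' @param x Numeric vector of angles in degrees.
#' @return Angles mapped into the interval (-180, 180]; exactly -180 maps
#'   to +180.
#' @export
wrap_deg <- function(x) {
  if (!all(is.finite(x))) stop("non-finite angle")
  x - 360 * ceiling((x - 180) / 360)
}

#' Signed circular difference a - b
#'
#' Difference between two angles mapped into (-180, 180] degrees, so that
#' e.g. `wrap_diff(10, 350)` is +20. Antisymmetric except on the +/-180
#' boundary, which maps to +180 by convention.
#'
#' @param a,b Angles in degrees (vectors are recycled).
#' @return Signed differences in degrees, in (-180, 180].
#' @export
wrap_diff <- function(a, b) {
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("non-finite angle")
  wrap_deg(a - b)
}

#' Circular mean and resultant length
#'
#' First trigonometric moment of a (possibly weighted) angular sample: the
#' mean direction is the argument of the weighted complex sum, the resultant
#' length R its modulus normalized by the total weight (0 = uniform,
#' 1 = fully concentrated).
#'
#' @param x Angles in degrees.
#' @param w Optional non-negative weights (same length as `x`).
#' @return List with `mean_deg` (in (-180, 180]) and `R` in `[0, 1]`.
#' @export
circ_mean_resultant <- function(x, w = NULL) {
  if (length(x) == 0L) stop("empty angular sample")
  if (!all(is.finite(x))) stop("non-finite angle")
  if (is.null(w)) w <- rep(1, length(x))
  if (length(w) != length(x)) stop("weights length mismatch")
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and non-negative")
  sw <- sum(w)
  if (sw <= 0) stop("weights sum to zero")
  th <- deg2rad(x)
  z <- sum(w * exp(1i * th)) / sw
  list(mean_deg = wrap_deg(rad2deg(Arg(z))), R = min(Mod(z), 1))
}

#' Circular-circular correlation (Fisher-Lee)
#'
#' The Fisher-Lee circular correlation coefficient
#' \deqn{\rho = \frac{\sum \sin(x_i - \bar x)\sin(y_i - \bar y)}
#'  {\sqrt{\sum \sin^2(x_i - \bar x)\sum \sin^2(y_i - \bar y)}}}
#' with \eqn{\bar x, \bar y} the circular means. Invariant under rotation of
#' either variable; +1 for y = x, -1 for y = -x.
#'
#' @param x,y Paired angles in degrees, length >= 3.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
circ_corr <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 paired angles")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite angle")
  mx <- circ_mean_resultant(x)$mean_deg
  my <- circ_mean_resultant(y)$mean_deg
  sx <- sin(deg2rad(x - mx))
  sy <- sin(deg2rad(y - my))
  den <- sqrt(sum(sx^2) * sum(sy^2))
  if (den < .Machine$double.eps^0.75) stop("constant angular input")
  max(-1, min(1, sum(sx * sy) / den))
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null of a uniform distribution on the circle against a
#' unimodal alternative. Z = n R^2; the p-value uses the standard
#' small-sample-corrected approximation
#' \eqn{p = \exp(\sqrt{1 + 4n + 4(n^2 - R_n^2)} - (1 + 2n))} with
#' \eqn{R_n = nR}.
#'
#' @param x Angles in degrees, n >= 5.
#' @return List with `R` (resultant length), `Z` (test statistic) and
#'   `p.value`.
#' @export
rayleigh_test <- function(x) {
  n <- length(x)
  if (n < 5L) stop("Rayleigh test needs n >= 5")
  R <- circ_mean_resultant(x)$R
  Rn <- n * R
  Z <- n * R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  list(R = R, Z = Z, p.value = max(0, min(1, p)))
}

## circular standard deviation (degrees) from a resultant length
circ_sd_deg <- function(R) {
  R <- max(min(R, 1), .Machine$double.xmin)
  rad2deg(sqrt(-2 * log(R)))
}

## Maximum-likelihood-style inversion of the von Mises A1 function:
## estimate concentration kappa from a resultant length (Fisher 1993).
kappa_from_R <- function(R) {
  R <- pmin(pmax(R, 0), 1 - 1e-12)
  ifelse(R < 0.53,
         2 * R + R^3 + 5 * R^5 / 6,
         ifelse(R < 0.85,
                -0.4 + 1.39 * R + 0.43 / (1 - R),
                1 / (R^3 - 4 * R^2 + 3 * R)))
}

## unwrap a degree series into a continuous trace (NA-tolerant for leading
## values only)
unwrap_deg <- function(x) {
  if (length(x) <= 1L) return(x)
  x[1] + c(0, cumsum(wrap_deg(diff(x))))
}
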