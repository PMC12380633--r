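#' Mean-field shared-input fraction
#'
#' Fraction of presynaptic inputs shared by two neurons at distance \code{d}
#' in a homogeneous spatial network whose connection probability decays as
#' \eqn{e^{-\lambda d}}: \eqn{K \approx e^{-2 \lambda d}}.
#'
#' @param lambda decay rate, 1/mm (nonnegative).
#' @param d distance, mm (nonnegative).
#' @return value in (0, 1].
#' @export
shared_input_fraction <- function(lambda, d) {
  if (any(lambda < 0)) stop("'lambda' must be nonnegative")
  if (any(d < 0)) stop("distances must be nonnegative")
  exp(-2 * lambda * d)
}

check_meanfield <- function(J, sigma2) {
  if (any(sigma2 < 0)) stop("'sigma2' must be nonnegative")
  if (any(sigma2 == 0 & J == 0))
    stop("correlation undefined for J = 0 with zero noise variance")
  invisible(TRUE)
}

#' Weak-coupling mean-field correlation
#'
#' Predicted pairwise spike-count correlation for two neurons at distance
#' \code{d} receiving shared input under weak coupling:
#' \deqn{C(d) = \frac{J^2}{J^2 + \sigma^2} e^{-2\lambda d}.}
#' As \eqn{\lambda \to 0} the correlation approaches its upper bound
#' \eqn{J^2/(J^2+\sigma^2)}; for large \eqn{\lambda d} it vanishes.
#'
#' @param J mean synaptic strength.
#' @param sigma2 noise variance of the shared input (> 0 unless J != 0).
#' @param lambda spatial decay of connectivity, 1/mm.
#' @param d distance, mm.
#' @return predicted correlation.
#' @examples
#' predicted_correlation(J = 1, sigma2 = 1, lambda = 1, d = 1)  # 0.5 * exp(-2)
#' @export
predicted_correlation <- function(J, sigma2, lambda, d) {
  check_meanfield(J, sigma2)
  if (any(lambda < 0) || any(d < 0)) stop("'lambda' and 'd' must be nonnegative")
  J^2 / (J^2 + sigma2) * exp(-2 * lambda * d)
}

#' Saturating mean-field correlation
#'
#' The alternative closed form in which the shared-input term enters both
#' numerator and denominator:
#' \deqn{C(d) = \frac{J^2 e^{-2\lambda d}}{J^2 e^{-2\lambda d} + \sigma^2}.}
#' It coincides with \code{\link{predicted_correlation}} at \eqn{\lambda = 0}
#' and to first order whenever \eqn{J^2 e^{-2\lambda d} \ll \sigma^2}.
#'
#' @inheritParams predicted_correlation
#' @return predicted correlation.
#' @export
predicted_correlation_saturating <- function(J, sigma2, lambda, d) {
  check_meanfield(J, sigma2)
  if (any(lambda < 0) || any(d < 0)) stop("'lambda' and 'd' must be nonnegative")
  s <- J^2 * exp(-2 * lambda * d)
  s / (s + sigma2)
}
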