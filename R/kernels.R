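## Parametric distance-decay families W(d) shared by the generative models,
## the raster-only maximum-likelihood estimator and the spatial GLM.

KERNEL_FAMILIES <- c("exponential", "half_gaussian", "linear",
                     "inverse_square", "lognormal")

## Canonical name of the free scale parameter of each family.
kernel_param_name <- function(family) {
  switch(family,
         exponential = "lambda",
         half_gaussian = "sigma",
         linear = "sigma",
         inverse_square = "sigma",
         lognormal = "sigma",
         stop("unknown kernel family: ", family))
}

#' Distance-decay kernels
#'
#' Constructs a parametric kernel W(d) mapping intersomatic distance (mm) to
#' an interaction weight. Available families:
#' \describe{
#'   \item{exponential}{\eqn{W(d) = e^{-\lambda d}}, \code{lambda} in 1/mm;
#'     \code{1/lambda} is the characteristic length scale.}
#'   \item{half_gaussian}{\eqn{W(d) = e^{-d^2/(2\sigma^2)}}, \code{sigma} in mm.}
#'   \item{linear}{\eqn{W(d) = \max(0, 1 - \sigma d)}, \code{sigma} in 1/mm.
#'     The raw form goes negative beyond \code{1/sigma}; weights double as
#'     probabilities and interaction strengths, so they are clipped at 0.}
#'   \item{inverse_square}{\eqn{W(d) = 1/(d^2 + \sigma)}, \code{sigma} in mm^2.}
#'   \item{lognormal}{\eqn{W(d) = \frac{1}{d\sigma\sqrt{2\pi}}
#'     e^{-(\log d^2 - \mu)^2 / (2\sigma^2)}} with dimensionless
#'     \code{sigma}, \code{mu}. \code{mu} is conventionally fixed from the
#'     geometry via \code{\link{fix_lognormal_mu}} so that only \code{sigma}
#'     is estimated. At \code{d = 0} the weight is undefined (1/d factor);
#'     it is returned as 0 with a warning and coincident pairs must be
#'     excluded from likelihoods.}
#' }
#'
#' @param family one of \code{"exponential"}, \code{"half_gaussian"},
#'   \code{"linear"}, \code{"inverse_square"}, \code{"lognormal"}.
#' @param lambda,sigma,mu family parameters (see Details). All scale
#'   parameters must be positive.
#' @return object of class \code{decay_kernel}.
#' @examples
#' k <- decay_kernel("exponential", lambda = 5)
#' kernel_weight(k, 0.2)  # exp(-1)
#' @export
decay_kernel <- function(family = KERNEL_FAMILIES, lambda = NULL, sigma = NULL,
                         mu = NULL) {
  family <- match.arg(family)
  scale <- switch(family, exponential = lambda, sigma)
  pname <- kernel_param_name(family)
  if (is.null(scale))
    stop(sprintf("family '%s' needs parameter '%s'", family, pname))
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop(sprintf("'%s' must be a single positive number", pname))
  params <- stats::setNames(list(scale), pname)
  if (family == "lognormal") {
    if (is.null(mu) || !is.finite(mu))
      stop("lognormal kernel needs a finite 'mu' (see fix_lognormal_mu())")
    params$mu <- mu
  }
  structure(list(family = family, params = params), class = "decay_kernel")
}

#' @export
print.decay_kernel <- function(x, ...) {
  cat(sprintf("decay_kernel: %s(%s)\n", x$family,
              paste(sprintf("%s = %g", names(x$params), unlist(x$params)),
                    collapse = ", ")))
  invisible(x)
}

#' Evaluate a decay kernel
#'
#' Vectorised evaluation of W(d); evaluating a matrix of distances returns a
#' matrix of weights.
#'
#' @param kernel a \code{\link{decay_kernel}}.
#' @param d nonnegative distances in mm (vector or matrix).
#' @return nonnegative weights, same shape as \code{d}.
#' @export
kernel_weight <- function(kernel, d) {
  stopifnot(inherits(kernel, "decay_kernel"))
  if (any(d < 0, na.rm = TRUE)) stop("distances must be nonnegative")
  p <- kernel$params
  w <- switch(kernel$family,
    exponential = exp(-p$lambda * d),
    half_gaussian = exp(-d^2 / (2 * p$sigma^2)),
    linear = pmax(0, 1 - p$sigma * d),
    inverse_square = 1 / (d^2 + p$sigma),
    lognormal = {
      out <- d
      zero <- d == 0
      if (any(zero)) {
        warning("lognormal kernel undefined at d = 0; returning 0 for coincident pairs")
        out[zero] <- 0
      }
      dd <- d[!zero]
      out[!zero] <- 1 / (dd * p$sigma * sqrt(2 * pi)) *
        exp(-(log(dd^2) - p$mu)^2 / (2 * p$sigma^2))
      out
    })
  if (is.matrix(d) && !is.matrix(w)) dim(w) <- dim(d)
  w
}

## dW/dtheta, theta the free scale parameter; same shapes as kernel_weight.
## Needed for the analytic gradients of the spatial GLM.
kernel_weight_deriv <- function(kernel, d) {
  p <- kernel$params
  w <- kernel_weight(kernel, d)
  switch(kernel$family,
    exponential = -d * w,
    half_gaussian = w * d^2 / p$sigma^3,
    linear = ifelse(1 - p$sigma * d > 0, -d, 0),
    inverse_square = -w^2,
    lognormal = {
      out <- d * 0
      nz <- d > 0
      dd <- d[nz]
      out[nz] <- w[nz] * (-1 / p$sigma + (log(dd^2) - p$mu)^2 / p$sigma^3)
      out
    })
}

#' Exponential connection probability
#'
#' Probability that an ordered pair of neurons at distance \code{d} mm is
#' connected, \eqn{P(J_{ij} = 1) = e^{-\lambda d}}.
#'
#' @param lambda decay rate in 1/mm (nonnegative; 0 gives all-to-all).
#' @param d distance in mm (nonnegative).
#' @return probability in (0, 1].
#' @export
connection_probability <- function(lambda, d) {
  if (any(lambda < 0)) stop("'lambda' must be nonnegative")
  if (any(d < 0)) stop("distances must be nonnegative")
  exp(-lambda * d)
}

#' Fix the lognormal location parameter from the geometry
#'
#' The lognormal kernel has two parameters; to estimate only its width
#' \code{sigma}, the location \code{mu} is fixed to the mean of
#' \eqn{\log d_{ij}} over all ordered pairs \eqn{i \neq j}.
#'
#' @param geom a \code{\link{pairwise_distances}} geometry with at least two
#'   neurons and no coincident pair.
#' @return the fixed \code{mu}.
#' @export
fix_lognormal_mu <- function(geom) {
  stopifnot(is_geometry(geom))
  n <- nrow(geom$positions)
  if (n < 2L) stop("need at least two neurons")
  d <- geom$distances
  off <- d[row(d) != col(d)]
  if (any(off == 0)) {
    idx <- which(d == 0 & row(d) != col(d), arr.ind = TRUE)[1, ]
    stop(sprintf("coincident neurons %d and %d (distance 0); lognormal mu undefined",
                 idx[1], idx[2]))
  }
  mean(log(off))
}
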