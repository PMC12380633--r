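#' Place neurons uniformly in a rectangular domain
#'
#' Positions are i.i.d. uniform over a finite rectangle (or box); boundaries
#' do not wrap around.
#'
#' @param n number of neurons (>= 1).
#' @param domain extents in mm: length 2 (width, height) or 3 for a box.
#'   Default the 1 x 1 mm square, the scale of a cortical two-photon field
#'   of view.
#' @param seed optional integer; when given, \code{set.seed(seed)} is called
#'   first so placement is reproducible.
#' @return a \code{\link{pairwise_distances}} geometry.
#' @export
place_neurons <- function(n, domain = c(1, 1), seed = NULL) {
  if (n < 1) stop("need at least one neuron")
  if (any(!is.finite(domain)) || any(domain <= 0))
    stop("domain extents must be positive")
  if (!length(domain) %in% c(2L, 3L))
    stop("domain must have 2 or 3 extents")
  if (!is.null(seed)) set.seed(seed)
  pos <- vapply(domain, function(ext) stats::runif(n, 0, ext),
                numeric(n))
  if (n == 1L) pos <- matrix(pos, nrow = 1)
  pairwise_distances(pos)
}

#' Sample distance-dependent binary connectivity
#'
#' Each ordered pair (j presynaptic, i postsynaptic), j != i, is connected
#' independently with probability \code{kernel_weight(kernel, d_ij)}, clipped
#' to [0, 1] (some families, e.g. inverse-square with small \code{sigma},
#' exceed 1 at short range). The diagonal is zero: no self-connections.
#'
#' @param geom a geometry.
#' @param kernel a \code{\link{decay_kernel}}; for exponential decay this is
#'   the connection rule \eqn{P(J_{ij}=1) = e^{-\lambda d_{ij}}}.
#' @param seed optional integer seed.
#' @return binary integer matrix (class \code{connectivity_matrix});
#'   \code{J[i, j] = 1} means j projects to i.
#' @export
sample_connectivity <- function(geom, kernel, seed = NULL) {
  stopifnot(is_geometry(geom))
  if (!is.null(seed)) set.seed(seed)
  if (kernel$family == "lognormal") {
    d <- geom$distances
    if (any(d[row(d) != col(d)] == 0))
      stop("coincident neurons: lognormal kernel undefined at d = 0")
  }
  p <- suppressWarnings(kernel_weight(kernel, geom$distances))
  if (any(!is.finite(p)) || any(p < 0))
    stop("kernel produced invalid connection probabilities")
  p <- pmin(p, 1)
  diag(p) <- 0
  n <- nrow(p)
  J <- matrix(as.integer(stats::runif(n * n) < p), n, n)
  diag(J) <- 0L
  class(J) <- c("connectivity_matrix", class(J))
  J
}

#' Linear Poisson network configuration
#'
#' Settings for the stochastic spiking network in which a neuron's per-bin
#' spike probability is its baseline plus the coupled activity of its
#' presynaptic partners one bin earlier. One bin corresponds to 1 ms.
#'
#' @param n_neurons network size.
#' @param domain rectangle extents in mm.
#' @param kernel connection kernel (default exponential, lambda = 5/mm).
#' @param r0 baseline: a spike probability per 1-ms bin for the linear link
#'   (default 0.002, i.e. about 2 Hz, the few-Hz regime of cortical data);
#'   on the logit scale for the logistic link (use e.g. -6, about 0.0025
#'   per bin).
#' @param alpha coupling strength. \code{NULL} (default) picks a
#'   size-stable coupling: for the linear link, scaled to the sampled
#'   network so that the branching ratio \code{alpha * mean in-degree}
#'   equals \code{branching} (a fixed \code{alpha} with a dense network
#'   otherwise saturates the link); for the logistic link, \code{100 / n},
#'   which keeps the total recurrent drive independent of network size and
#'   the quiescent state stable against population bursts.
#' @param branching target branching ratio used when \code{alpha} is
#'   \code{NULL} (default 0.4, comfortably subcritical).
#' @param T_ms duration in ms.
#' @param link \code{"linear_clipped"} (the generative rule:
#'   \code{clip(r0 + alpha * J \%*\% S)}) or \code{"logistic"}
#'   (\code{sigmoid(r0 + alpha * sum_j S_j(t-1) W(d_ij))}, the form assumed
#'   by the three-parameter spatial GLM; note the logistic model couples all
#'   pairs through the kernel weight rather than through sampled synapses).
#' @param seed integer seed.
#' @return list of class \code{poisson_net_config}.
#' @export
poisson_net_config <- function(n_neurons = 1000, domain = c(1, 1),
                               kernel = decay_kernel("exponential", lambda = 5),
                               r0 = 0.002, alpha = NULL, branching = 0.4,
                               T_ms = 1e5,
                               link = c("linear_clipped", "logistic"),
                               seed = 1) {
  link <- match.arg(link)
  if (n_neurons < 2) stop("need at least two neurons")
  if (link == "linear_clipped" && (r0 < 0 || r0 >= 1))
    stop("'r0' must lie in [0, 1) for the linear link")
  if (!is.finite(r0)) stop("'r0' must be finite")
  if (!is.null(alpha) && alpha < 0) stop("'alpha' must be nonnegative")
  structure(list(n_neurons = n_neurons, domain = domain, kernel = kernel,
                 r0 = r0, alpha = alpha, branching = branching, T_ms = T_ms,
                 link = link, seed = seed),
            class = "poisson_net_config")
}

#' Simulate the linear Poisson network
#'
#' Runs the discrete-time update: at each 1-ms bin, neuron i spikes with
#' probability \code{clip(r0 + alpha * sum_j J_ij S_j(t-1), 0, 1)} (linear
#' link) or \code{sigmoid(r0 + alpha * sum_j W_ij S_j(t-1))} (logistic link,
#' which uses kernel weights in place of sampled synapses and therefore
#' needs \code{geom}). The first bin uses the baseline alone.
#'
#' @param J binary connectivity from \code{\link{sample_connectivity}}
#'   (ignored under the logistic link).
#' @param config a \code{\link{poisson_net_config}}.
#' @param geom geometry; required for the logistic link.
#' @return a \code{\link{spike_raster}} (bin 1 ms) with attribute
#'   \code{alpha} giving the effective coupling used.
#' @export
simulate_poisson <- function(J, config, geom = NULL) {
  stopifnot(inherits(config, "poisson_net_config"))
  logistic <- config$link == "logistic"
  if (logistic) {
    if (is.null(geom)) stop("logistic link needs the geometry")
    M <- kernel_weight(config$kernel, geom$distances)
    diag(M) <- 0
  } else {
    if (is.null(dim(J)) || nrow(J) != ncol(J)) stop("J must be square")
    M <- J
    storage.mode(M) <- "double"
  }
  n <- nrow(M)
  if (n != config$n_neurons)
    stop("network size does not match config$n_neurons")
  alpha <- config$alpha
  if (is.null(alpha)) {
    if (logistic) {
      ## keep the total recurrent drive alpha * N * E[W] size-independent
      ## and small enough that the low-rate fixed point is metastable
      alpha <- 100 / n
    } else {
      indeg <- mean(rowSums(M))
      alpha <- if (indeg <= 0) 0 else config$branching / indeg
    }
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  ev <- cpp_simulate_net(M, config$r0, alpha, as.integer(config$T_ms), logistic)
  sp <- Matrix::sparseMatrix(i = ev$i, j = ev$t, x = 1,
                             dims = c(n, as.integer(config$T_ms)))
  r <- spike_raster(sp, bin_ms = 1)
  attr(r, "alpha") <- alpha
  r
}

#' One-call Poisson-network dataset
#'
#' Places neurons, samples connectivity from the configured kernel, and
#' simulates the raster; the standard way to create a synthetic dataset
#' with known ground truth.
#'
#' @param config a \code{\link{poisson_net_config}}.
#' @return list with \code{geom}, \code{J}, \code{raster}, \code{alpha}
#'   (effective coupling) and \code{config}.
#' @examples
#' sim <- simulate_poisson_network(poisson_net_config(n_neurons = 50, T_ms = 1000))
#' sim$raster
#' @export
simulate_poisson_network <- function(config) {
  stopifnot(inherits(config, "poisson_net_config"))
  set.seed(config$seed)
  geom <- place_neurons(config$n_neurons, config$domain)
  J <- sample_connectivity(geom, config$kernel)
  raster <- simulate_poisson(J, config_no_reseed(config), geom)
  list(geom = geom, J = J, raster = raster, alpha = attr(raster, "alpha"),
       config = config)
}

## internal: copy of a config whose seed is NULL so a wrapper that already
## seeded the stream does not reset it mid-run
config_no_reseed <- function(config) {
  config$seed <- NULL
  config
}
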