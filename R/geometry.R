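#' Neuron geometry: positions and pairwise distances
#'
#' Holds per-neuron somatic coordinates in millimetres (2-D or 3-D) together
#' with the full symmetric Euclidean distance matrix. Distances are stored
#' dense; memory grows as the square of the number of neurons (about 0.8 GB
#' at 10,000 neurons), which is acceptable at the population sizes targeted
#' here.
#'
#' @param positions numeric matrix (or data frame), neurons x dimensions
#'   (2 or 3 columns), coordinates in mm.
#' @return object of class \code{geometry} with elements \code{positions}
#'   and \code{distances}.
#' @examples
#' g <- pairwise_distances(rbind(c(0, 0), c(0.003, 0.004)))
#' g$distances[1, 2]  # 0.005 mm
#' @export
pairwise_distances <- function(positions) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (nrow(positions) < 1L)
    stop("need at least one neuron")
  if (!ncol(positions) %in% c(2L, 3L))
    stop("positions must have 2 or 3 coordinate columns")
  if (!all(is.finite(positions)))
    stop("non-finite coordinates")
  d <- as.matrix(stats::dist(positions))
  dimnames(d) <- NULL
  structure(list(positions = positions, distances = d),
            class = "geometry")
}

#' @rdname pairwise_distances
#' @export
geometry <- pairwise_distances

is_geometry <- function(x) inherits(x, "geometry")

#' @export
print.geometry <- function(x, ...) {
  n <- nrow(x$positions)
  cat(sprintf("geometry: %d neurons in %d-D (mm)\n", n, ncol(x$positions)))
  if (n > 1) {
    ut <- x$distances[upper.tri(x$distances)]
    cat(sprintf("  pairwise distance: median %.3g mm, max %.3g mm\n",
                stats::median(ut), max(ut)))
  }
  invisible(x)
}

check_raster_geometry <- function(raster, geom) {
  if (raster$n_neurons != nrow(geom$positions))
    stop(sprintf("raster has %d neurons but geometry has %d",
                 raster$n_neurons, nrow(geom$positions)))
  invisible(TRUE)
}
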