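#' Spike raster objects
#'
#' A spike raster is a binary neurons x time-bins matrix at a fixed bin width.
#' Internally spikes are held as a sparse \code{\link[Matrix]{dgCMatrix}}
#' (column = time bin), which keeps hour-long recordings of thousands of
#' neurons in a few megabytes at the few-Hz rates typical of cortex.
#'
#' @param spikes binary matrix (dense or sparse), neurons in rows, time bins
#'   in columns. Entries must be 0 or 1.
#' @param bin_ms width of one time bin in milliseconds (default 1 ms; one
#'   time step of the generative models corresponds to one 1-ms bin).
#' @return An object of class \code{spike_raster} with elements
#'   \code{spikes} (dgCMatrix), \code{bin_ms}, \code{n_neurons},
#'   \code{n_bins} and \code{t_total_ms}.
#' @examples
#' r <- spike_raster(matrix(c(0, 1, 1, 0), 2, 2), bin_ms = 1)
#' r$t_total_ms
#' @export
spike_raster <- function(spikes, bin_ms = 1) {
  if (!is.numeric(bin_ms) || length(bin_ms) != 1L || !is.finite(bin_ms) || bin_ms <= 0)
    stop("'bin_ms' must be a single positive number")
  if (inherits(spikes, "lgCMatrix") || inherits(spikes, "ngCMatrix"))
    spikes <- methods::as(spikes, "dMatrix")
  if (is.matrix(spikes)) {
    if (!all(spikes %in% c(0, 1)))
      stop("raster entries must be 0 or 1")
    spikes <- methods::as(methods::as(Matrix::Matrix(spikes, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  }
  if (!inherits(spikes, "dgCMatrix"))
    spikes <- methods::as(methods::as(spikes, "generalMatrix"), "CsparseMatrix")
  if (length(spikes@x) && !all(spikes@x %in% c(0, 1)))
    stop("raster entries must be 0 or 1")
  spikes <- Matrix::drop0(spikes)
  if (nrow(spikes) < 1L || ncol(spikes) < 1L)
    stop("raster needs at least one neuron and one time bin")
  structure(list(
    spikes = spikes,
    bin_ms = bin_ms,
    n_neurons = nrow(spikes),
    n_bins = ncol(spikes),
    t_total_ms = ncol(spikes) * bin_ms
  ), class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  rate <- sum(x$spikes) / x$n_neurons / (x$t_total_ms / 1000)
  cat(sprintf("spike_raster: %d neurons x %d bins (%.3g ms/bin, %.3g s)\n",
              x$n_neurons, x$n_bins, x$bin_ms, x$t_total_ms / 1000))
  cat(sprintf("  %d spikes, population rate %.3g Hz\n", sum(x$spikes), rate))
  invisible(x)
}

is_spike_raster <- function(x) inherits(x, "spike_raster")

## Column-compressed spike coordinates for the C++ kernels.
raster_colptr <- function(raster) raster$spikes@p
raster_rowidx <- function(raster) raster$spikes@i

## Sum spikes into non-overlapping counting windows of m bins each.
## Returns a sparse neurons x n_windows count matrix; trailing bins that do
## not fill a complete window are dropped.
bin_counts <- function(raster, count_bin_ms) {
  m <- count_bin_ms / raster$bin_ms
  if (abs(m - round(m)) > 1e-9 || m < 1)
    stop("'count_bin_ms' must be a positive integer multiple of the raster bin width")
  m <- as.integer(round(m))
  n_win <- raster$n_bins %/% m
  if (n_win < 1L)
    stop("raster is shorter than one counting window")
  t_use <- n_win * m
  agg <- Matrix::sparseMatrix(i = seq_len(t_use),
                              j = rep(seq_len(n_win), each = m),
                              x = 1, dims = c(t_use, n_win))
  raster$spikes[, seq_len(t_use), drop = FALSE] %*% agg
}

#' Raster diagnostics: rates, Fano factors, correlations, synchrony
#'
#' Summarises a spike raster by per-neuron firing rates, Fano factors of
#' spike counts in non-overlapping windows (variance over mean; ~1 for
#' Poisson-like trains), the mean pairwise Pearson correlation of counts,
#' and a synchrony histogram (number of counting windows in which a given
#' number of population spikes occurred).
#'
#' Silent neurons have an undefined Fano factor; they are flagged (\code{NA})
#' and excluded from the mean. Pairs in which either neuron has zero count
#' variance are likewise excluded from the mean correlation rather than
#' counted as zero, which would otherwise bias the summary toward 0 in
#' sparsely firing populations.
#'
#' @param raster a \code{\link{spike_raster}}.
#' @param count_bin_ms counting-window width in ms (default 10 ms); must be
#'   an integer multiple of the raster bin width.
#' @param max_corr_neurons cap on the number of neurons entering the
#'   pairwise-correlation summary (random subset above this; the full
#'   correlation matrix is quadratic in neurons). Default 2000.
#' @return object of class \code{raster_diagnostics}.
#' @export
raster_diagnostics <- function(raster, count_bin_ms = 10, max_corr_neurons = 2000L) {
  stopifnot(is_spike_raster(raster))
  counts <- bin_counts(raster, count_bin_ms)
  n_win <- ncol(counts)
  n <- raster$n_neurons

  total <- Matrix::rowSums(raster$spikes)
  rate_hz <- total / (raster$t_total_ms / 1000)
  silent <- total == 0

  cs <- Matrix::rowSums(counts)
  mu <- cs / n_win
  ssq <- Matrix::rowSums(counts^2)
  vr <- (ssq - n_win * mu^2) / (n_win - 1)
  fano <- ifelse(cs > 0, vr / mu, NA_real_)

  ## Pairwise correlations on the counting windows.
  idx <- which(!silent)
  if (length(idx) > max_corr_neurons) {
    idx <- sort(sample(idx, max_corr_neurons))
  }
  mean_corr <- NA_real_
  n_pairs_used <- 0L
  corr_sub <- NULL
  if (length(idx) >= 2L && n_win >= 2L) {
    ## zero-variance neurons yield NA correlations (excluded below)
    cm <- suppressWarnings(
      stats::cor(t(as.matrix(counts[idx, , drop = FALSE]))))
    ut <- cm[upper.tri(cm)]
    ok <- is.finite(ut)
    n_pairs_used <- sum(ok)
    if (n_pairs_used > 0L) mean_corr <- mean(ut[ok])
    corr_sub <- idx
  }

  pop <- Matrix::colSums(counts)
  sync <- tabulate(pop + 1L, nbins = max(pop) + 1L)
  names(sync) <- as.character(0:max(pop))

  structure(list(
    mean_rate_hz = list(per_neuron = rate_hz, population = mean(rate_hz)),
    fano_factors = fano,
    mean_fano = if (all(is.na(fano))) NA_real_ else mean(fano, na.rm = TRUE),
    silent = silent,
    mean_pairwise_correlation = mean_corr,
    n_pairs_used = n_pairs_used,
    correlation_neurons = corr_sub,
    synchrony_histogram = sync,
    count_bin_ms = count_bin_ms
  ), class = "raster_diagnostics")
}

#' @export
print.raster_diagnostics <- function(x, ...) {
  cat(sprintf("raster diagnostics (counting bin %g ms)\n", x$count_bin_ms))
  cat(sprintf("  population rate : %.3g Hz (%d silent neurons)\n",
              x$mean_rate_hz$population, sum(x$silent)))
  cat(sprintf("  mean Fano factor: %.3g\n", x$mean_fano))
  cat(sprintf("  mean pairwise correlation: %.4g (%d pairs)\n",
              x$mean_pairwise_correlation, x$n_pairs_used))
  invisible(x)
}
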