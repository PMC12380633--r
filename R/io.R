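## Plain-text I/O for rasters and positions. Two raster formats, both
## round-trippable: a sparse event list (neuron_id, time_ms) and a dense
## 0/1 matrix, each carrying n/bin metadata in '#' header lines. Files
## ending in .gz are transparently compressed.

open_read <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}
open_write <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

header_meta <- function(lines) {
  h <- grep("^#", lines, value = TRUE)
  kv <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*[:=]\\s*(\\S+)", h))
  kv <- Filter(function(x) length(x) == 3, kv)
  stats::setNames(vapply(kv, `[`, "", 3), vapply(kv, `[`, "", 2))
}

#' Save and load spike rasters
#'
#' \code{save_raster} writes a raster either as a sparse event list
#' (columns \code{neuron_id}, \code{time_ms}; the time is the start of the
#' spike's bin) or as a dense 0/1 matrix with neurons in rows. Metadata
#' (neuron count, bin count, bin width) travels in \code{#} header lines,
#' so a save/load round trip reproduces the raster exactly. Paths ending in
#' \code{.gz} are compressed.
#'
#' @param raster a \code{\link{spike_raster}}.
#' @param path output file.
#' @param format \code{"events"} (default) or \code{"dense"}.
#' @return \code{path}, invisibly.
#' @export
save_raster <- function(raster, path, format = c("events", "dense")) {
  stopifnot(is_spike_raster(raster))
  format <- match.arg(format)
  con <- open_write(path)
  on.exit(close(con))
  if (format == "events") {
    ev <- Matrix::summary(raster$spikes)
    ev <- ev[order(ev$j, ev$i), , drop = FALSE]
    writeLines(c("# spatdecay raster events",
                 sprintf("# n_neurons=%d", raster$n_neurons),
                 sprintf("# n_bins=%d", raster$n_bins),
                 sprintf("# bin_ms=%.17g", raster$bin_ms),
                 "neuron_id,time_ms"), con)
    if (nrow(ev))
      writeLines(sprintf("%d,%.17g", ev$i, (ev$j - 1) * raster$bin_ms), con)
  } else {
    writeLines(c("# spatdecay raster dense",
                 sprintf("# bin_ms=%.17g", raster$bin_ms)), con)
    m <- as.matrix(raster$spikes)
    utils::write.table(m, con, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' @rdname save_raster
#' @details \code{load_raster} detects the format from the first header
#'   line. Event times are binned half-open: an event at time \code{t} ms
#'   falls in bin \code{floor(t / bin_ms) + 1}, so 0 and 0.999 ms land in
#'   the first 1-ms bin and 1.0 ms in the second. Events at or beyond the
#'   declared duration, or at negative times, are errors.
#' @export
load_raster <- function(path) {
  con <- open_read(path)
  on.exit(close(con))
  lines <- readLines(con)
  meta <- header_meta(lines)
  body <- lines[!grepl("^#", lines)]
  if (length(lines) == 0 || !grepl("^# spatdecay raster", lines[1]))
    stop("not a spatdecay raster file: ", path)
  bin_ms <- as.numeric(meta[["bin_ms"]])
  if (grepl("events", lines[1])) {
    n <- as.integer(meta[["n_neurons"]])
    nb <- as.integer(meta[["n_bins"]])
    df <- utils::read.csv(text = body, header = TRUE)
    if (nrow(df)) {
      if (any(df$time_ms < 0)) stop("negative event times")
      if (any(df$time_ms >= nb * bin_ms))
        stop("event beyond the declared duration")
      if (any(df$neuron_id < 1 | df$neuron_id > n))
        stop("neuron id outside 1..n_neurons")
      bin <- floor(df$time_ms / bin_ms) + 1
      keep <- !duplicated(cbind(df$neuron_id, bin))
      sp <- Matrix::sparseMatrix(i = df$neuron_id[keep], j = bin[keep], x = 1,
                                 dims = c(n, nb))
    } else {
      sp <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                 x = numeric(0), dims = c(n, nb))
    }
    spike_raster(sp, bin_ms)
  } else {
    m <- as.matrix(utils::read.table(text = body, sep = ","))
    dimnames(m) <- NULL
    spike_raster(m, bin_ms)
  }
}

#' Save and load neuron positions
#'
#' Positions travel as CSV with columns \code{id}, \code{x}, \code{y}
#' (and optionally \code{z}) plus a mandatory \code{# units: mm} (or
#' \code{um}) header; micrometre files are converted to mm on load
#' (exact division by 1000). Units are never guessed. Rows are aligned to
#' raster neuron order by \code{id}, so a shuffled file loads identically.
#'
#' @param geom a geometry.
#' @param path file path.
#' @return \code{save_positions}: \code{path} invisibly;
#'   \code{load_positions}: a \code{\link{pairwise_distances}} geometry.
#' @export
save_positions <- function(geom, path) {
  stopifnot(is_geometry(geom))
  con <- open_write(path)
  on.exit(close(con))
  writeLines("# units: mm", con)
  df <- data.frame(id = seq_len(nrow(geom$positions)), geom$positions)
  names(df) <- c("id", c("x", "y", "z")[seq_len(ncol(geom$positions))])
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_positions
#' @export
load_positions <- function(path) {
  con <- open_read(path)
  on.exit(close(con))
  lines <- readLines(con)
  meta <- header_meta(lines)
  units <- if ("units" %in% names(meta)) meta[["units"]] else NULL
  if (is.null(units) || is.na(units))
    stop("positions file must declare units ('# units: mm' or um)")
  if (!units %in% c("mm", "um"))
    stop("unknown position units: ", units)
  df <- utils::read.csv(text = lines[!grepl("^#", lines)], header = TRUE)
  if (anyDuplicated(df$id)) stop("duplicate neuron ids in positions file")
  df <- df[order(df$id), , drop = FALSE]
  cols <- intersect(c("x", "y", "z"), names(df))
  pos <- as.matrix(df[, cols, drop = FALSE])
  dimnames(pos) <- NULL
  if (units == "um") pos <- pos / 1000
  pairwise_distances(pos)
}

#' Reproducible synthetic fixtures on disk
#'
#' Simulates a small dataset and writes raster, positions and a
#' ground-truth JSON (generating kernel, parameters, seed) into a
#' directory. Byte-identical for a given seed. Kinds:
#' \describe{
#'   \item{poisson}{linear Poisson network
#'     (params: \code{n}, \code{lambda}, \code{r0}, \code{T_ms}).}
#'   \item{izhikevich}{Izhikevich network
#'     (params: \code{n}, \code{lambda}, \code{T_ms}).}
#'   \item{paired_toy}{two neurons where the second copies the first with a
#'     one-bin lag (params: \code{p} spike probability, \code{T_ms});
#'     closed-form reference input for transfer entropy and Granger tests.}
#' }
#'
#' @param kind fixture kind.
#' @param params named list overriding the defaults above.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
make_fixture <- function(kind = c("poisson", "izhikevich", "paired_toy"),
                         params = list(), seed = 1, dir = tempfile("fixture")) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  getp <- function(name, default) {
    if (!is.null(params[[name]])) params[[name]] else default
  }
  if (kind == "poisson") {
    cfg <- poisson_net_config(
      n_neurons = getp("n", 200),
      kernel = decay_kernel("exponential", lambda = getp("lambda", 5)),
      r0 = getp("r0", 0.002), T_ms = getp("T_ms", 1e4), seed = seed)
    sim <- simulate_poisson_network(cfg)
    truth <- list(kind = kind, family = "exponential",
                  lambda = cfg$kernel$params$lambda, r0 = cfg$r0,
                  alpha = sim$alpha, n_neurons = cfg$n_neurons,
                  T_ms = cfg$T_ms, seed = seed)
    raster <- sim$raster; geom <- sim$geom
  } else if (kind == "izhikevich") {
    cfg <- izhikevich_config(n_neurons = getp("n", 200),
                             lambda = getp("lambda", 5),
                             T_ms = getp("T_ms", 1e4), seed = seed)
    sim <- simulate_izhikevich_network(cfg)
    truth <- list(kind = kind, family = "exponential", lambda = cfg$lambda,
                  base_sparsity = cfg$base_sparsity, c_w = cfg$c_w,
                  n_neurons = cfg$n_neurons, T_ms = cfg$T_ms, seed = seed)
    raster <- sim$raster; geom <- sim$geom
  } else {
    p <- getp("p", 0.3)
    T_ms <- getp("T_ms", 1e4)
    set.seed(seed)
    x <- as.integer(stats::runif(T_ms) < p)
    y <- c(0L, x[-T_ms])
    raster <- spike_raster(rbind(x, y), bin_ms = 1)
    geom <- pairwise_distances(rbind(c(0, 0), c(0.1, 0)))
    truth <- list(kind = kind, p = p, lag_bins = 1, T_ms = T_ms, seed = seed)
  }
  paths <- c(raster = file.path(dir, "raster.csv"),
             positions = file.path(dir, "positions.csv"),
             truth = file.path(dir, "truth.json"))
  save_raster(raster, paths[["raster"]])
  save_positions(geom, paths[["positions"]])
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}
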