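#' Multisource concentration timeseries
#'
#' Container for a samples x sources matrix of odour concentrations measured
#' at a common probe, together with the sample rate, the 2-D coordinates of
#' each source, and the pitch (the obstacle spacing of the flow, used as the
#' natural length unit for intersource separations).
#'
#' @param values numeric matrix, samples x sources (arbitrary concentration
#'   units). Column names, if present, label the sources.
#' @param sample_rate sampling rate in Hz (> 0).
#' @param positions numeric matrix, sources x 2, the (x, y) coordinates of
#'   each source in metres. A numeric vector is taken as the y-coordinates
#'   of sources at x = 0.
#' @param pitch length normalizer in metres (> 0); separations divided by
#'   the pitch are in "pitch units".
#' @param label free-text description.
#'
#' @return An object of class `plume_series`.
#' @export
plume_series <- function(values, sample_rate, positions, pitch = 1,
                         label = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(dim(positions))) {
    positions <- cbind(x = 0, y = as.numeric(positions))
  }
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L)
    stop("`positions` must have one (x, y) row per source")
  if (nrow(positions) != ncol(values))
    stop("`positions` must have one entry per source (column of `values`)")
  if (ncol(values) < 2L)
    stop("need at least 2 sources")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("`sample_rate` must be a single positive number (Hz)")
  if (!is.numeric(pitch) || length(pitch) != 1L || pitch <= 0)
    stop("`pitch` must be a single positive number (metres)")
  colnames(positions) <- c("x", "y")
  structure(
    list(values = values, sample_rate = sample_rate, positions = positions,
         pitch = pitch, label = as.character(label)),
    class = "plume_series"
  )
}

#' @export
print.plume_series <- function(x, ...) {
  cat("<plume_series>", if (nzchar(x$label)) x$label else NULL, "\n")
  cat(sprintf("  %d samples x %d sources @ %g Hz (%.2f s)\n",
              nrow(x$values), ncol(x$values), x$sample_rate,
              nrow(x$values) / x$sample_rate))
  cat(sprintf("  pitch: %g m; source y-range: [%g, %g] m\n",
              x$pitch, min(x$positions[, "y"]), max(x$positions[, "y"])))
  invisible(x)
}

#' Analysis window specification
#'
#' @param length_s window length in seconds.
#' @param shape `"boxcar"`, `"hann"`, or `"kaiser"`.
#' @param overlap overlap as a fraction of the window length; segments are
#'   advanced by `length_s * (1 - overlap)`. Default 0.5 (half-window
#'   overlap).
#' @param kaiser_beta Kaiser shape parameter; default 16.
#'
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length_s = 1, shape = c("boxcar", "hann", "kaiser"),
                        overlap = 0.5, kaiser_beta = 16) {
  shape <- match.arg(shape)
  stopifnot(length_s > 0, overlap >= 0, overlap < 1, kaiser_beta >= 0)
  structure(list(length_s = length_s, shape = shape, overlap = overlap,
                 kaiser_beta = kaiser_beta),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  shape <- if (x$shape == "kaiser")
    sprintf("kaiser(beta=%g)", x$kaiser_beta) else x$shape
  cat(sprintf("<window_spec> %g s %s, overlap %g\n", x$length_s, shape,
              x$overlap))
  invisible(x)
}

#' Window weights for a given segment length
#'
#' Hann weights use the periodic convention `0.5 - 0.5 cos(2 pi t / L)`;
#' Kaiser weights are `I0(beta sqrt(1 - (2t/(L-1) - 1)^2)) / I0(beta)`.
#'
#' @param spec a [window_spec()].
#' @param n segment length in samples (>= 4).
#' @return numeric vector of `n` weights.
#' @export
window_weights <- function(spec, n) {
  stopifnot(inherits(spec, "window_spec"), n >= 4)
  t <- seq_len(n) - 1
  switch(spec$shape,
    boxcar = rep(1, n),
    hann = 0.5 - 0.5 * cos(2 * pi * t / n),
    kaiser = {
      b <- spec$kaiser_beta
      arg <- b * sqrt(pmax(0, 1 - (2 * t / (n - 1) - 1)^2))
      besselI(arg, 0) / besselI(b, 0)
    })
}

#' Read a multisource concentration CSV with a JSON metadata sidecar
#'
#' The CSV holds one column per source; the sidecar (same path with
#' extension `.json`, or given explicitly) holds `sample_rate`, `pitch`,
#' `positions` (list of \[x, y\] pairs) and optionally `label`.
#'
#' @param csv path to the CSV file.
#' @param sidecar path to the JSON sidecar; default replaces the CSV
#'   extension with `.json`.
#' @return a [plume_series()].
#' @export
read_plume_csv <- function(csv, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sub("\\.[^.]+$", ".json", csv)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  values <- as.matrix(utils::read.csv(csv, check.names = FALSE))
  plume_series(values, sample_rate = meta$sample_rate,
               positions = matrix(unlist(meta$positions), ncol = 2,
                                  byrow = !is.matrix(meta$positions)),
               pitch = meta$pitch,
               label = if (!is.null(meta$label)) meta$label else "")
}

#' Write a multisource concentration CSV with a JSON metadata sidecar
#'
#' @param series a [plume_series()].
#' @param csv output CSV path; the sidecar is written next to it.
#' @return invisibly, the sidecar path.
#' @export
write_plume_csv <- function(series, csv) {
  stopifnot(inherits(series, "plume_series"))
  utils::write.csv(series$values, csv, row.names = FALSE)
  sidecar <- sub("\\.[^.]+$", ".json", csv)
  jsonlite::write_json(
    list(sample_rate = series$sample_rate, pitch = series$pitch,
         positions = unname(series$positions), label = series$label),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}
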