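#' Spike raster container
#'
#' Per-neuron ordered spike-time lists with E/I population labels over a
#' simulation window.  This is the common currency between the simulator,
#' the synthetic raster generators and all measures.
#'
#' @param spikes list of numeric vectors, one strictly increasing spike-time
#'   vector (ms) per neuron.
#' @param population character vector of `"E"` / `"I"` labels, one per
#'   neuron.
#' @param duration raster duration, ms; all spike times must lie in
#'   `[0, duration]`.
#' @param origin optional free-form provenance string (e.g. a config hash).
#' @return Object of class `spike_raster`.
#' @export
spike_raster <- function(spikes, population, duration, origin = NULL) {
  stopifnot(is.list(spikes), length(spikes) == length(population),
            all(population %in% c("E", "I")), duration > 0)
  for (i in seq_along(spikes)) {
    s <- spikes[[i]]
    if (length(s) && (is.unsorted(s, strictly = TRUE) || s[1] < 0 ||
                      s[length(s)] > duration))
      stop("spike train ", i, " is not strictly increasing within [0, ",
           duration, "]", call. = FALSE)
  }
  structure(list(spikes = spikes, population = as.character(population),
                 duration = duration, origin = origin),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  nE <- sum(x$population == "E"); nI <- sum(x$population == "I")
  cat("<spike_raster> ", nE, " E + ", nI, " I cells, ", x$duration,
      " ms, ", sum(lengths(x$spikes)), " spikes\n", sep = "")
  invisible(x)
}

#' Subset a raster to one population
#'
#' @param raster a [spike_raster()].
#' @param population `"E"` or `"I"`.
#' @return List of spike-time vectors for the selected cells.
#' @export
population_spikes <- function(raster, population = c("E", "I")) {
  population <- match.arg(population)
  raster$spikes[raster$population == population]
}

#' Write / read a raster as JSON
#'
#' Plain-text serialization carrying spikes, labels and duration; the
#' companion [write_raster_csv()] emits the two-column plotting dialect.
#'
#' @param raster a [spike_raster()].
#' @param path file path.
#' @return `read_raster_json()` returns a [spike_raster()];
#'   `write_raster_json()` returns `path` invisibly.
#' @export
write_raster_json <- function(raster, path) {
  jsonlite::write_json(
    list(duration = raster$duration, population = raster$population,
         origin = raster$origin, spikes = raster$spikes),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_raster_json
#' @export
read_raster_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spikes <- lapply(x$spikes, as.numeric)
  spike_raster(spikes, x$population, x$duration, origin = x$origin)
}

#' Write a raster as a two-column CSV
#'
#' Emits `neuron_index,spike_time_ms` rows for plotting.  Excitatory cells
#' are ordered by descending drive current when `drive` is supplied, so the
#' most strongly driven cells get the lowest indices.
#'
#' @inheritParams write_raster_json
#' @param drive optional per-cell drive currents used to order the
#'   excitatory cells (descending).
#' @export
write_raster_csv <- function(raster, path, drive = NULL) {
  idx <- seq_along(raster$spikes)
  if (!is.null(drive)) {
    e <- which(raster$population == "E")
    i <- which(raster$population == "I")
    idx[e[order(drive[e], decreasing = TRUE)]] <- seq_along(e)
    idx[i] <- length(e) + seq_along(i)
  }
  df <- data.frame(
    neuron_index = rep(idx, lengths(raster$spikes)),
    spike_time_ms = unlist(raster$spikes, use.names = FALSE))
  utils::write.csv(df[order(df$neuron_index, df$spike_time_ms), ],
                   path, row.names = FALSE)
  invisible(path)
}
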