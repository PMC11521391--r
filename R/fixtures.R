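# Synthetic rasters with known ground truth.  These emulate the burst
# structure of simulated rasters (spike packets with jitter, background
# firing) without any membrane dynamics, so the measures layer can be
# validated against construction.

#' Synthetic raster of jittered spike packets
#'
#' Each participating cell emits one spike per packet at the packet time
#' plus independent Gaussian jitter, and every cell additionally fires
#' homogeneous-Poisson background spikes.  Ground-truth packet times are
#' attached, so burst-detection accuracy can be scored exactly.
#'
#' @param n_cells number of cells.
#' @param packet_times packet (burst) times, ms.
#' @param participation fraction of cells participating in each packet
#'   (cells drawn independently per packet).
#' @param jitter per-spike Gaussian jitter SD, ms.
#' @param background_rate Poisson background rate per cell, Hz.
#' @param duration raster duration, ms; default covers the packets.
#' @param population label for all cells, `"E"` or `"I"`.
#' @param seed integer seed.
#' @return A [spike_raster()] with attribute `packet_times`.
#' @examples
#' ras <- make_burst_raster(100, c(200, 400, 600), jitter = 1, seed = 1)
#' burst_detect(ras, "E", window = c(0, 700), threshold = 5)
#' @export
make_burst_raster <- function(n_cells, packet_times, participation = 1,
                              jitter = 0, background_rate = 0,
                              duration = NULL, population = "E",
                              seed = 1L) {
  stopifnot(participation >= 0, participation <= 1, jitter >= 0,
            background_rate >= 0, n_cells >= 1)
  if (is.null(duration)) duration <- max(packet_times) + 100
  set.seed(seed)
  spikes <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    s <- numeric(0)
    for (p in packet_times) {
      if (stats::runif(1) < participation) {
        t <- p + if (jitter > 0) stats::rnorm(1, 0, jitter) else 0
        s <- c(s, t)
      }
    }
    if (background_rate > 0) {
      nb <- stats::rpois(1, background_rate * duration / 1000)
      s <- c(s, stats::runif(nb, 0, duration))
    }
    s <- sort(s[s >= 0 & s <= duration])
    spikes[[i]] <- s[!duplicated(s)]
  }
  ras <- spike_raster(spikes, rep(population, n_cells), duration,
                      origin = sprintf("burst fixture seed %d", seed))
  attr(ras, "packet_times") <- packet_times
  ras
}

#' Synthetic asynchronous raster
#'
#' Independent homogeneous Poisson spike trains, the reference for the
#' `S -> 0` limit of the synchrony measure.
#'
#' @inheritParams make_burst_raster
#' @param rate firing rate per cell, Hz.
#' @return A [spike_raster()].
#' @export
make_async_raster <- function(n_cells, rate, duration, population = "E",
                              seed = 1L) {
  stopifnot(rate >= 0, duration > 0, n_cells >= 1)
  set.seed(seed)
  spikes <- lapply(seq_len(n_cells), function(i) {
    k <- stats::rpois(1, rate * duration / 1000)
    s <- sort(stats::runif(k, 0, duration))
    s[!duplicated(s)]
  })
  spike_raster(spikes, rep(population, n_cells), duration,
               origin = sprintf("async fixture seed %d", seed))
}
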