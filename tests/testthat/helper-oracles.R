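# Independent brute-force oracles for the measures layer.  These evaluate
# the defining formulas directly (full outer products, explicit sums) and
# deliberately share no code with the package's optimized implementations.

# Sum of Gaussian kernels over all spikes at every grid point, no
# truncation or incremental tricks.
oracle_kernel_trace <- function(spikes, grid, denom = 1.6) {
  if (length(spikes) == 0L) return(numeric(length(grid)))
  rowSums(exp(-outer(grid, spikes, "-")^2 / denom))
}

# Direct evaluation of the variance-ratio synchrony measure: per-cell
# convolved traces, population mean, variance ratio.  Cells silent in the
# window are excluded.
oracle_synchrony <- function(raster, population = "E", window,
                             kernel_sd = sqrt(0.8), grid_dt = 0.1) {
  spk <- lapply(population_spikes(raster, population),
                function(s) s[s >= window[1] & s <= window[2]])
  spk <- spk[lengths(spk) > 0L]
  if (length(spk) == 0L) return(NA_real_)
  grid <- seq(window[1], window[2], by = grid_dt)
  traces <- sapply(spk, oracle_kernel_trace, grid = grid,
                   denom = 2 * kernel_sd^2)
  pvar <- function(x) mean(x^2) - mean(x)^2
  pvar(rowMeans(traces)) / mean(apply(traces, 2, pvar))
}

# Explicit double-exponential sum over a spike list (the accumulator
# recursion in the integrator must agree with this).
oracle_synapse_sum <- function(spike_times, t, tau_d, tau_r) {
  s <- spike_times[spike_times <= t]
  sum(exp(-(t - s) / tau_d) - exp(-(t - s) / tau_r))
}

# A hand-made burst_set for testing the burst statistics in isolation.
fake_burst_set <- function(onset, offset) {
  structure(data.frame(onset = onset, offset = offset,
                       center = (onset + offset) / 2),
            threshold = 1, population = "E", window = c(0, 1000),
            class = c("burst_set", "data.frame"))
}

type1 <- function() neuron_params(gKs = 0)
type2 <- function() neuron_params(gKs = 1.5)

# Small network configurations used across simulator tests.
tiny_config <- function(...) {
  network_config(n_exc = 20, n_inh = 5, ...)
}
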