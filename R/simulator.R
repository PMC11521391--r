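#' Network simulation settings
#'
#' Integration and synapse parameters for [run_simulation()].  Synaptic
#' currents follow a double-exponential conductance kernel
#' `exp(-(t-s)/tau_d) - exp(-(t-s)/tau_r)` summed over presynaptic spikes
#' `s`; the sum is maintained by an exact two-accumulator exponential
#' recursion.  Spikes do not drive synapses until `synapse_onset` (100 ms
#' by default) so that initial transients decay first.
#'
#' @param duration simulation length, ms.
#' @param dt RK4 step, ms.
#' @param synapse_onset time before which spikes trigger no synaptic
#'   current, ms.
#' @param tau_r synaptic rise time, ms (all synapses).
#' @param tau_d_exc,tau_d_inh synaptic decay times, ms, for excitatory and
#'   inhibitory synapses.
#' @param Esyn_exc,Esyn_inh synaptic reversal potentials, mV.
#' @param record integer vector of cell indices whose voltage traces to
#'   record (1-based), or `NULL`.
#' @param seed integer seed for the random initial conditions.
#' @return Object of class `simulation_settings`.
#' @export
simulation_settings <- function(duration = 1500, dt = 0.05,
                                synapse_onset = 100,
                                tau_r = 0.2, tau_d_exc = 3.0,
                                tau_d_inh = 5.5,
                                Esyn_exc = 0, Esyn_inh = -75,
                                record = NULL, seed = 1L) {
  stopifnot(dt > 0, duration > dt, synapse_onset < duration,
            tau_r > 0, tau_r < tau_d_exc, tau_r < tau_d_inh)
  structure(list(duration = duration, dt = dt, synapse_onset = synapse_onset,
                 tau_r = tau_r, tau_d_exc = tau_d_exc, tau_d_inh = tau_d_inh,
                 Esyn_exc = Esyn_exc, Esyn_inh = Esyn_inh,
                 record = record, seed = as.integer(seed)),
            class = "simulation_settings")
}

#' Draw random initial conditions for a population of cells
#'
#' Voltages uniform on (-62, -22) mV, `h` and `n` uniform on (0.2, 0.8),
#' `z` uniform on (0.15, 0.25); independent across cells.  Consumes the
#' current RNG state.
#'
#' @param n number of cells.
#' @return `n x 4` matrix with columns `V`, `h`, `n`, `z`.
#' @export
draw_initial_state <- function(n) {
  cbind(V = stats::runif(n, -62, -22),
        h = stats::runif(n, 0.2, 0.8),
        n = stats::runif(n, 0.2, 0.8),
        z = stats::runif(n, 0.15, 0.25))
}

# flatten a list-of-target-vectors into 0-based CSR, offsetting targets
.csr <- function(targets, offset = 0L) {
  lens <- lengths(targets)
  list(ptr = as.integer(c(0L, cumsum(lens))),
       idx = as.integer(unlist(targets, use.names = FALSE) - 1L + offset))
}

#' Evaluate the double-exponential synaptic current
#'
#' Direct evaluation of the synaptic current at time `t` given a list of
#' presynaptic spike times: `Isyn = gsyn (V - Esyn) sum_i [exp(-(t-s_i)/tau_d)
#' - exp(-(t-s_i)/tau_r)]` over spikes `s_i <= t`.  The network integrator
#' maintains this sum incrementally with two exponential accumulators; this
#' function is the explicit form used for inspection and as the
#' accumulators' reference.
#'
#' @param spike_times presynaptic spike times, ms.
#' @param t evaluation time, ms.
#' @param V_post postsynaptic membrane voltage, mV.
#' @param gsyn maximal synaptic conductance, mS/cm^2.
#' @param Esyn synaptic reversal potential, mV.
#' @param tau_r,tau_d rise and decay time constants, ms.
#' @return Synaptic current, uA/cm^2.
#' @export
synaptic_current <- function(spike_times, t, V_post, gsyn, Esyn,
                             tau_r = 0.2, tau_d = 5.5) {
  s <- spike_times[spike_times <= t]
  if (length(s) == 0L) return(0)
  gsyn * (V_post - Esyn) * sum(exp(-(t - s) / tau_d) - exp(-(t - s) / tau_r))
}

#' Time of the double-exponential kernel peak
#'
#' Closed-form maximum location of `exp(-t/tau_d) - exp(-t/tau_r)` after a
#' spike at `t = 0`.
#'
#' @inheritParams synaptic_current
#' @return Peak time in ms.
#' @export
synaptic_peak_time <- function(tau_r, tau_d) {
  tau_d * tau_r / (tau_d - tau_r) * log(tau_d / tau_r)
}

#' Simulate an E-I network
#'
#' Advances every cell with fixed-step RK4 under its drive current and the
#' recurrent synaptic currents, from random initial conditions, and
#' returns the spike raster.  Spikes are detected as upward 0 mV crossings
#' with a 2 ms lockout; synaptic kernels are frozen at their step-start
#' values within each RK4 step (the synaptic time constants are two orders
#' of magnitude larger than `dt`).
#'
#' @param network a [build_network()] result.
#' @param settings a [simulation_settings()] object.
#' @return A [spike_raster()]; when `settings$record` is non-`NULL` it
#'   carries a `traces` attribute (matrix, one column per recorded cell)
#'   and a `time` attribute.
#' @examples
#' \donttest{
#' net <- build_network(network_config(n_exc = 40, n_inh = 10, seed = 1))
#' ras <- run_simulation(net, simulation_settings(duration = 400, seed = 1))
#' ras
#' }
#' @export
run_simulation <- function(network, settings = simulation_settings()) {
  stopifnot(inherits(network, "network_model"),
            inherits(settings, "simulation_settings"))
  cfg <- network$config
  nE <- cfg$n_exc; nI <- cfg$n_inh; N <- nE + nI
  set.seed(settings$seed)
  init <- draw_initial_state(N)
  # merge per-presynaptic-cell targets across the two postsynaptic
  # populations into absolute indices
  exc_targets <- lapply(seq_len(nE), function(j)
    c(network$adjacency$EE[[j]], network$adjacency$EI[[j]] + nE))
  inh_targets <- if (nI > 0) lapply(seq_len(nI), function(j)
    c(network$adjacency$IE[[j]], network$adjacency$II[[j]] + nE)) else list()
  ce <- .csr(exc_targets)
  ci <- .csr(inh_targets)
  rec <- if (is.null(settings$record)) integer(0)
         else as.integer(settings$record) - 1L
  res <- .sim_network_cpp(nE, nI,
                          unclass(network$params_exc), unclass(network$params_inh),
                          network$drive, init,
                          ce$ptr, ce$idx, ci$ptr, ci$idx,
                          network$g[["EE"]], network$g[["EI"]],
                          network$g[["IE"]], network$g[["II"]],
                          settings$duration, settings$dt,
                          settings$synapse_onset,
                          settings$tau_r, settings$tau_d_exc,
                          settings$tau_d_inh,
                          settings$Esyn_exc, settings$Esyn_inh,
                          rec)
  if (!res$ok)
    stop("network integration blew up at step ", res$bad_step,
         " (t = ", res$bad_step * settings$dt, " ms), cell ",
         res$bad_cell + 1L, call. = FALSE)
  ras <- spike_raster(res$spikes,
                      c(rep("E", nE), rep("I", nI)),
                      settings$duration,
                      origin = sprintf("seed %d/%d", cfg$seed, settings$seed))
  if (length(rec)) {
    attr(ras, "traces") <- res$traces
    attr(ras, "time") <- seq(0, by = settings$dt, length.out = nrow(res$traces))
  }
  ras
}
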