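#' Parameters of the M-current pyramidal-cell model
#'
#' Constructs the parameter set of the Hodgkin-Huxley style cortical
#' pyramidal cell used for every neuron in the network.  The single
#' modulation knob is `gKs`, the maximal conductance of the slow M-type
#' potassium current: `gKs = 0` corresponds to complete muscarinic blockade
#' of the M-current (high acetylcholine) and yields Type I excitability;
#' `gKs = 1.5` corresponds to a fully active M-current (low acetylcholine)
#' and yields Type II excitability.
#'
#' @param gKs M-current maximal conductance, mS/cm^2.  `0` (Type I) and
#'   `1.5` (Type II) are the two standard modulation states; other
#'   non-negative values are accepted with a warning.
#' @param gNa,gKd,gL maximal conductances of the sodium, delayed-rectifier
#'   potassium and leak currents, mS/cm^2.
#' @param ENa,EK,EL reversal potentials, mV.
#' @return An object of class `neuron_params`: a named numeric vector with
#'   elements `gNa`, `gKd`, `gKs`, `gL`, `ENa`, `EK`, `EL`.
#' @examples
#' type1 <- neuron_params(gKs = 0)
#' type2 <- neuron_params(gKs = 1.5)
#' @export
neuron_params <- function(gKs = 0, gNa = 24, gKd = 3, gL = 0.02,
                          ENa = 55, EK = -90, EL = -60) {
  g <- c(gNa = gNa, gKd = gKd, gKs = gKs, gL = gL)
  if (any(!is.finite(g)) || any(g < 0))
    stop("conductances must be finite and non-negative", call. = FALSE)
  if (!gKs %in% c(0, 1.5))
    warning("gKs = ", gKs, " is outside the two standard modulation states ",
            "(0 = Type I, 1.5 = Type II)", call. = FALSE)
  p <- c(g, ENa = ENa, EK = EK, EL = EL)
  class(p) <- "neuron_params"
  p
}

#' @export
print.neuron_params <- function(x, ...) {
  type <- if (x[["gKs"]] == 0) "Type I (M-current blocked)"
          else if (x[["gKs"]] == 1.5) "Type II (M-current active)"
          else "nonstandard gKs"
  cat("<neuron_params> ", type, "\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Initial state of a model neuron
#'
#' @param V membrane voltage, mV.
#' @param h,n,z gating variables in \[0, 1\] (sodium inactivation,
#'   delayed-rectifier activation, M-current activation).  Defaults are the
#'   steady-state values at `V`.
#' @return Named numeric vector `(V, h, n, z)` of class `neuron_state`.
#' @export
neuron_state <- function(V = -70, h = NULL, n = NULL, z = NULL) {
  if (!is.finite(V)) stop("V must be finite", call. = FALSE)
  ss <- steady_state_gates(V)
  h <- if (is.null(h)) ss[["h"]] else h
  n <- if (is.null(n)) ss[["n"]] else n
  z <- if (is.null(z)) ss[["z"]] else z
  gv <- c(h = h, n = n, z = z)
  if (any(gv < 0) || any(gv > 1))
    stop("gating variables must lie in [0, 1]", call. = FALSE)
  st <- c(V = V, gv)
  class(st) <- "neuron_state"
  st
}

#' Steady-state gating values
#'
#' Voltage-dependent fixed points of the four gating variables.  Sodium
#' activation `m` is instantaneous in this model, so `m = m_inf(V)` enters
#' the membrane equation directly and is not a state variable.
#'
#' @param V membrane voltage, mV (vectorized).
#' @return For scalar `V` a named vector `(m, h, n, z)`; otherwise a matrix
#'   with one row per voltage.
#' @examples
#' steady_state_gates(-30)[c("m", "n")]  # both sigmoid midpoints: 0.5
#' @export
steady_state_gates <- function(V) {
  if (any(!is.finite(V))) stop("V must be finite", call. = FALSE)
  out <- .gate_steady_cpp(as.numeric(V))
  if (length(V) == 1L) out[1L, ] else out
}

#' Gating time constants
#'
#' Voltage-dependent relaxation times of `h`, `n` and `z` in ms.  The
#' M-current gate relaxes with a fixed slow time constant of 75 ms, which is
#' what produces spike-frequency adaptation when `gKs > 0`.
#'
#' @inheritParams steady_state_gates
#' @return For scalar `V` a named vector `(h, n, z)`; otherwise a matrix.
#' @export
gate_time_constants <- function(V) {
  if (any(!is.finite(V))) stop("V must be finite", call. = FALSE)
  out <- .gate_tau_cpp(as.numeric(V))
  if (length(V) == 1L) out[1L, ] else out
}

#' Time-derivative of the neuron state
#'
#' Right-hand side of the model: the membrane equation (with membrane
#' capacitance 1 uF/cm^2) plus first-order relaxation of the three gating
#' variables towards their steady states.
#'
#' @param state a [neuron_state()] vector `(V, h, n, z)`.
#' @param params a [neuron_params()] object.
#' @param Iapp applied (drive) current, uA/cm^2.
#' @param Isyn synaptic current, uA/cm^2 (positive = outward, i.e. it is
#'   subtracted from the membrane equation).
#' @return Named vector of derivatives `(V, h, n, z)` in mV/ms and 1/ms.
#' @export
membrane_derivative <- function(state, params, Iapp = 0, Isyn = 0) {
  stopifnot(inherits(params, "neuron_params"))
  .deriv_cpp(as.numeric(state), unclass(params), Iapp, Isyn)
}

#' Integrate a single isolated neuron
#'
#' Fixed-step classical Runge-Kutta (RK4) integration of one model neuron
#' under constant drive, with optional square current pulse (used by the
#' phase-response protocol).  Spikes are detected as upward crossings of
#' 0 mV with a 2 ms lockout; the recorded spike time is the end of the
#' crossing step.
#'
#' @inheritParams membrane_derivative
#' @param duration simulation length, ms.
#' @param dt integration step, ms (default 0.05).
#' @param init initial [neuron_state()].
#' @param pulse optional `list(start =, duration =, amplitude =)` describing
#'   a square current pulse in ms / uA/cm^2.
#' @param record_trace if `TRUE`, return the voltage trace.
#' @return List with `spikes` (ms, strictly increasing), `state` (final
#'   state), and optionally `V` (voltage at each step) and `time`.
#' @examples
#' p <- neuron_params(gKs = 0)
#' sim <- simulate_single_neuron(p, Iapp = 0.5, duration = 500)
#' length(sim$spikes)
#' @export
simulate_single_neuron <- function(params, Iapp, duration, dt = 0.05,
                                   init = neuron_state(), pulse = NULL,
                                   record_trace = FALSE) {
  stopifnot(inherits(params, "neuron_params"), dt > 0, duration > dt)
  ps <- if (is.null(pulse)) c(0, 0, 0)
        else c(pulse$start, pulse$duration, pulse$amplitude)
  res <- .sim_neuron_cpp(unclass(params), Iapp, duration, dt,
                         as.numeric(init), ps[1], ps[2], ps[3], record_trace)
  if (!res$ok)
    stop("integration blew up (non-finite state) at step ", res$bad_step,
         " (t = ", res$bad_step * dt, " ms)", call. = FALSE)
  out <- list(spikes = res$spikes, state = res$state)
  if (record_trace) {
    out$V <- res$V; out$h <- res$h; out$n <- res$n; out$z <- res$z
    out$time <- seq(0, by = dt, length.out = length(res$V))
  }
  out
}

#' Steady firing rate of a spike train
#'
#' Rate over a trailing analysis window, computed as
#' `(count - 1) / (last - first)` from the spikes inside the window; `0`
#' when fewer than two spikes fall in the window.  Using the inter-spike
#' span rather than the window length avoids partial-period bias.
#'
#' @param spikes spike times, ms.
#' @param window `c(start, end)` analysis window, ms.
#' @return Rate in Hz.
#' @export
steady_rate <- function(spikes, window) {
  s <- spikes[spikes >= window[1] & spikes <= window[2]]
  if (length(s) < 2L) return(0)
  1000 * (length(s) - 1L) / (s[length(s)] - s[1L])
}

.rate_at_current <- function(params, Iapp, duration = 2000, dt = 0.05,
                             transient = 500) {
  sim <- simulate_single_neuron(params, Iapp, duration, dt)
  steady_rate(sim$spikes, c(transient, duration))
}

#' Current-frequency (I-F) curve
#'
#' Steady firing rate of an isolated neuron across a grid of drive
#' currents.  Type I cells (`gKs = 0`) have a continuous I-F curve with
#' arbitrarily low onset rate; Type II cells (`gKs = 1.5`) switch on at a
#' nonzero minimum rate.
#'
#' @inheritParams simulate_single_neuron
#' @param currents ascending grid of drive currents, uA/cm^2.
#' @param duration,transient per-current simulation length and discarded
#'   transient, ms.
#' @return `data.frame(current, rate)` with rates in Hz.
#' @export
fi_curve <- function(params, currents, duration = 2000, dt = 0.05,
                     transient = 500) {
  stopifnot(!is.unsorted(currents))
  rates <- vapply(currents, function(I)
    .rate_at_current(params, I, duration, dt, transient), numeric(1))
  data.frame(current = currents, rate = rates)
}

# deterministic bisection results are reused across sweep cells
.calibration_cache <- new.env(parent = emptyenv())

#' Calibrate the drive current for a target firing rate
#'
#' Bisection on the drive current of an isolated neuron until its steady
#' firing rate is within `tol` of `target` (the I-F curve is monotone over
#' the bracket).  Deterministic, so repeated calls return the identical
#' current; results are memoised.
#'
#' @inheritParams simulate_single_neuron
#' @param target target steady rate, Hz.
#' @param tol rate tolerance, Hz (default 0.1).
#' @param bracket current interval known to straddle the target; default
#'   `c(0, 5)` for Type I and `c(0, 10)` for Type II cells.
#' @param max_iter bisection iteration cap.
#' @return Drive current in uA/cm^2.
#' @export
calibrate_drive <- function(params, target, tol = 0.1, bracket = NULL,
                            max_iter = 60, dt = 0.05) {
  stopifnot(inherits(params, "neuron_params"), target > 0, tol > 0)
  if (is.null(bracket))
    bracket <- if (params[["gKs"]] > 0) c(0, 10) else c(0, 5)
  key <- paste(format(c(unclass(params), target, tol, bracket, dt), digits = 15),
               collapse = "|")
  if (!is.null(.calibration_cache[[key]])) return(.calibration_cache[[key]])
  lo <- bracket[1]; hi <- bracket[2]
  r_lo <- .rate_at_current(params, lo, dt = dt)
  r_hi <- .rate_at_current(params, hi, dt = dt)
  if (r_lo > target || r_hi < target)
    stop("target rate ", target, " Hz not bracketed by currents [",
         lo, ", ", hi, "] (rates ", round(r_lo, 2), ", ", round(r_hi, 2),
         " Hz)", call. = FALSE)
  mid <- NA_real_
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r <- .rate_at_current(params, mid, dt = dt)
    if (abs(r - target) <= tol) break
    if (r < target) lo <- mid else hi <- mid
  }
  .calibration_cache[[key]] <- mid
  mid
}

#' Phase response curve
#'
#' First-order PRC of a periodically firing neuron: a brief square current
#' pulse is delivered at `n_phases` evenly spaced phases of the firing
#' cycle and the normalized change of the perturbed period is recorded,
#' `shift(phi) = (T0 - T_perturbed(phi)) / T0` (positive = phase advance).
#' Type I cells show only advances; Type II cells are delayed by pulses
#' early in the cycle.
#'
#' @inheritParams simulate_single_neuron
#' @param Iapp constant drive giving periodic firing, uA/cm^2.
#' @param pulse_amplitude pulse height, uA/cm^2 (default 2 with the 0.5 ms
#'   default duration injects 1 uC/cm^2 per pulse, a ~1 mV perturbation).
#' @param pulse_duration pulse length, ms.
#' @param n_phases number of evenly spaced stimulation phases.
#' @return Object of class `phase_response_curve`: `data.frame(phase,
#'   shift)` with attributes `period`, `pulse_amplitude`, `pulse_duration`.
#' @export
compute_prc <- function(params, Iapp, pulse_amplitude = 2,
                        pulse_duration = 0.5, n_phases = 50, dt = 0.05) {
  base <- simulate_single_neuron(params, Iapp, duration = 2000, dt = dt)
  sp <- base$spikes
  late <- sp[sp > 1000]
  if (length(late) < 6L)
    stop("baseline is not firing periodically at Iapp = ", Iapp,
         "; PRC undefined", call. = FALSE)
  T0 <- mean(diff(late))
  t_ref <- late[3L]  # reference spike, well past transient
  horizon <- t_ref + 3 * T0
  phases <- (seq_len(n_phases) - 0.5) / n_phases
  shifts <- vapply(phases, function(phi) {
    pert <- simulate_single_neuron(
      params, Iapp, duration = horizon, dt = dt,
      pulse = list(start = t_ref + phi * T0, duration = pulse_duration,
                   amplitude = pulse_amplitude))
    nxt <- pert$spikes[pert$spikes > t_ref + 1]
    if (length(nxt) == 0L) return(NA_real_)
    (T0 - (nxt[1L] - t_ref)) / T0
  }, numeric(1))
  out <- data.frame(phase = phases, shift = shifts)
  attr(out, "period") <- T0
  attr(out, "pulse_amplitude") <- pulse_amplitude
  attr(out, "pulse_duration") <- pulse_duration
  class(out) <- c("phase_response_curve", "data.frame")
  out
}
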