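#' E-I network configuration
#'
#' Describes a two-population network: sizes, cell types (Type I or II per
#' population), Bernoulli connection probabilities for the four directed
#' synapse classes, per-class maximal conductances and the drive-current
#' specification.  Defaults reproduce the reference network: 800 E + 200 I
#' cells, inter-connection probability 0.5 (E-I and I-E), intra-connection
#' probability 0.3 (E-E and I-I), excitatory drives calibrated to a
#' 45-55 Hz intrinsic-rate band, and inhibitory drives near threshold
#' (mean -0.2 uA/cm^2 for Type I, +1.0 for Type II interneurons, each
#' jittered uniformly by +/-5%).
#'
#' Inter-class conductances are varied jointly (`g_EI = g_IE = g_inter`)
#' and the E-E conductance defaults to a quarter of the I-I value,
#' matching the 4:1 excitatory/inhibitory cell-count ratio.
#'
#' `synapse_scale` compensates for network downscaling: in-degrees scale
#' with population size, so a network of `N` cells uses per-class
#' conductances multiplied by `1000 / N` to preserve the expected total
#' synaptic conductance per cell of the 1000-cell reference network.  At
#' full size the factor is 1.
#'
#' @param n_exc,n_inh population sizes.
#' @param exc_type,inh_type `"I"` or `"II"` excitability class per
#'   population (i.e. gKs = 0 or 1.5).
#' @param g_inter inter-population conductance (applied to both E-I and
#'   I-E), mS/cm^2.
#' @param g_II I-I conductance, mS/cm^2.
#' @param g_EE E-E conductance, mS/cm^2; default `g_II / 4`.
#' @param p_EI,p_IE,p_EE,p_II connection probabilities per directed class.
#' @param exc_rate_band `c(low, high)` intrinsic-rate band (Hz) defining
#'   the excitatory drive-current interval via [calibrate_drive()].
#' @param IA mean inhibitory drive current, uA/cm^2; default -0.2 for
#'   Type I and 1.0 for Type II interneurons.
#' @param synapse_scale conductance compensation factor; default
#'   `1000 / (n_exc + n_inh)`.
#' @param seed integer seed for wiring and drive draws.
#' @return Object of class `network_config`.
#' @export
network_config <- function(n_exc = 800, n_inh = 200,
                           exc_type = c("I", "II"), inh_type = c("I", "II"),
                           g_inter = 0.00175, g_II = 0.00025,
                           g_EE = g_II / 4,
                           p_EI = 0.5, p_IE = 0.5, p_EE = 0.3, p_II = 0.3,
                           exc_rate_band = c(45, 55), IA = NULL,
                           synapse_scale = 1000 / (n_exc + n_inh),
                           seed = 1L) {
  exc_type <- match.arg(exc_type)
  inh_type <- match.arg(inh_type)
  probs <- c(p_EI = p_EI, p_IE = p_IE, p_EE = p_EE, p_II = p_II)
  if (any(probs < 0 | probs > 1))
    stop("connection probabilities must lie in [0, 1]", call. = FALSE)
  if (any(c(g_inter, g_II, g_EE) < 0))
    stop("conductances must be non-negative", call. = FALSE)
  stopifnot(n_exc >= 1, n_inh >= 0, synapse_scale > 0,
            length(exc_rate_band) == 2, exc_rate_band[1] <= exc_rate_band[2])
  if (is.null(IA)) IA <- if (inh_type == "I") -0.2 else 1.0
  structure(list(n_exc = n_exc, n_inh = n_inh,
                 exc_type = exc_type, inh_type = inh_type,
                 g_inter = g_inter, g_II = g_II, g_EE = g_EE,
                 p_EI = p_EI, p_IE = p_IE, p_EE = p_EE, p_II = p_II,
                 exc_rate_band = exc_rate_band, IA = IA,
                 synapse_scale = synapse_scale, seed = as.integer(seed)),
            class = "network_config")
}

#' Desk-scale network preset
#'
#' A 200 E + 50 I network with the same connection probabilities, cell
#' types and drive specification as the full-size network, and synaptic
#' conductances compensated (x4) for the smaller in-degrees.
#'
#' @param ... arguments passed on to [network_config()].
#' @return A `network_config`.
#' @export
scaled_config <- function(...) network_config(n_exc = 200, n_inh = 50, ...)

#' @export
print.network_config <- function(x, ...) {
  cat("<network_config> ", x$n_exc, "E (Type ", x$exc_type, ") + ",
      x$n_inh, "I (Type ", x$inh_type, "); g_inter=", x$g_inter,
      " g_II=", x$g_II, " g_EE=", x$g_EE,
      " (scale x", x$synapse_scale, "); seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
print.network_model <- function(x, ...) {
  cat("<network_model> ", x$config$n_exc, "E + ", x$config$n_inh, "I; edges:",
      " E->E ", sum(lengths(x$adjacency$EE)),
      ", E->I ", sum(lengths(x$adjacency$EI)),
      ", I->E ", sum(lengths(x$adjacency$IE)),
      ", I->I ", sum(lengths(x$adjacency$II)), "\n", sep = "")
  invisible(x)
}

# Bernoulli adjacency: for each of n_pre presynaptic cells, the vector of
# postsynaptic indices (1-based within the postsynaptic population).
.bernoulli_targets <- function(n_pre, n_post, p, exclude_self = FALSE) {
  lapply(seq_len(n_pre), function(j) {
    hits <- which(stats::runif(n_post) < p)
    if (exclude_self) hits <- hits[hits != j]
    hits
  })
}

#' Draw the four synapse-class adjacencies
#'
#' Each potential directed edge is drawn independently as a Bernoulli
#' variable with its class probability; self-synapses are excluded within
#' E-E and I-I.  Consumes the current RNG state (seed it beforehand for
#' reproducibility).
#'
#' @param config a [network_config()].
#' @return List `EE`, `EI`, `IE`, `II`; each element is a list over
#'   presynaptic cells of postsynaptic index vectors (1-based within the
#'   target population).
#' @export
build_connectivity <- function(config) {
  stopifnot(inherits(config, "network_config"))
  list(EE = .bernoulli_targets(config$n_exc, config$n_exc, config$p_EE, TRUE),
       EI = .bernoulli_targets(config$n_exc, config$n_inh, config$p_EI),
       IE = .bernoulli_targets(config$n_inh, config$n_exc, config$p_IE),
       II = .bernoulli_targets(config$n_inh, config$n_inh, config$p_II, TRUE))
}

#' Draw heterogeneous excitatory drive currents
#'
#' Calibrates the currents at which an isolated excitatory cell fires at
#' the low and high ends of `exc_rate_band` (45 and 55 Hz by default) and
#' draws each cell's drive i.i.d. uniformly between them.
#'
#' @inheritParams build_connectivity
#' @return Numeric vector of length `n_exc` with attributes `Iapp_min`,
#'   `Iapp_max` (the calibrated interval endpoints).
#' @export
assign_excitatory_drive <- function(config) {
  stopifnot(inherits(config, "network_config"))
  p <- neuron_params(gKs = if (config$exc_type == "I") 0 else 1.5)
  lo <- calibrate_drive(p, config$exc_rate_band[1])
  hi <- if (config$exc_rate_band[2] == config$exc_rate_band[1]) lo
        else calibrate_drive(p, config$exc_rate_band[2])
  drives <- stats::runif(config$n_exc, lo, hi)
  attr(drives, "Iapp_min") <- lo
  attr(drives, "Iapp_max") <- hi
  drives
}

#' Draw inhibitory drive currents
#'
#' Each interneuron's drive is uniform on `[0.95 IA, 1.05 IA]` (endpoints
#' ordered numerically, so negative `IA` works).  The defaults keep
#' interneurons just below firing threshold: Type I cells fire
#' spontaneously and receive a small hyperpolarizing current, Type II
#' cells a small depolarizing one.
#'
#' @inheritParams build_connectivity
#' @return Numeric vector of length `n_inh`.
#' @export
assign_inhibitory_drive <- function(config) {
  stopifnot(inherits(config, "network_config"))
  bounds <- sort(c(0.95, 1.05) * config$IA)
  stats::runif(config$n_inh, bounds[1], bounds[2])
}

#' Build a complete network model
#'
#' Seeds the RNG from `config$seed`, draws wiring and drive currents, and
#' packages them with the per-population neuron parameters and effective
#' (compensation-scaled) per-class conductances.
#'
#' @inheritParams build_connectivity
#' @return Object of class `network_model` with elements `config`,
#'   `adjacency` (see [build_connectivity()]), `drive` (length
#'   `n_exc + n_inh`, E cells first), `params_exc`, `params_inh`, and `g`
#'   (named vector `EE`, `EI`, `IE`, `II` of effective conductances).
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  set.seed(config$seed)
  adjacency <- build_connectivity(config)
  drive_e <- assign_excitatory_drive(config)
  drive_i <- assign_inhibitory_drive(config)
  g <- config$synapse_scale *
    c(EE = config$g_EE, EI = config$g_inter, IE = config$g_inter,
      II = config$g_II)
  structure(list(
    config = config,
    adjacency = adjacency,
    drive = c(drive_e, drive_i),
    drive_bounds = c(attr(drive_e, "Iapp_min"), attr(drive_e, "Iapp_max")),
    params_exc = neuron_params(gKs = if (config$exc_type == "I") 0 else 1.5),
    params_inh = neuron_params(gKs = if (config$inh_type == "I") 0 else 1.5),
    g = g), class = "network_model")
}

#' Remove all I-to-E synapses from a network
#'
#' Sets the effective I-E conductance to zero, leaving the wiring (and
#' therefore every random draw) untouched, so the ablation is the only
#' difference from the intact network.
#'
#' @param network a [build_network()] result.
#' @return The modified `network_model`.
#' @export
ablate_IE <- function(network) {
  stopifnot(inherits(network, "network_model"))
  network$g[["IE"]] <- 0
  network
}
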