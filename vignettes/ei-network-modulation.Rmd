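---
title: "Cholinergic modulation, connectivity structure, and synchrony in E-I networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cholinergic modulation, connectivity structure, and synchrony in E-I networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific question

Acetylcholine (ACh) blocks the slow M-type potassium current of cortical
pyramidal cells and of several interneuron classes through muscarinic
receptors.  Removing this current changes three intrinsic properties at
once: the current-frequency (I-F) curve, spike-frequency adaptation, and
the phase response curve (PRC).  In the standard classification, a cell
with the M-current active is *Type II* (discontinuous I-F onset at a
nonzero minimum rate; PRC with an early-phase delay lobe) and the same
cell with the M-current blocked is *Type I* (continuous I-F onset at
arbitrarily low rate; all-advance PRC).  Type II cells synchronize more
readily through mutual excitation.

`pingnet` asks how this cellular switch interacts with the *connectivity
structure* of a recurrently coupled excitatory-inhibitory (E-I) network:
when does cholinergic modulation of either population decide whether the
excitatory population produces synchronous bursts, and when does network
wiring decide on its own?  The central contrast is between
*inter*-connectivity (E-I and I-E synapse classes, the backbone of the
Pyramidal-Interneuron Network Gamma, or PING, mechanism) and
*intra*-connectivity (E-E and I-I classes).

# The neuron model

All cells use one Hodgkin-Huxley style membrane model (capacitance
1 uF/cm^2):

$$\frac{dV}{dt} = -g_{Na} m_\infty^3 h (V - E_{Na}) - g_{Kd} n^4 (V - E_K)
 - g_{Ks} z (V - E_K) - g_L (V - E_L) + I_{app} - I_{syn}$$

with first-order kinetics $dX/dt = (X_\infty(V) - X)/\tau_X(V)$ for
$X \in \{h, n, z\}$ and instantaneous sodium activation $m =
m_\infty(V)$.  The gating sigmoids have midpoints at $-30$ mV ($m$, $n$),
$-53$ mV ($h$), and $-39$ mV ($z$); $\tau_h$ and $\tau_n$ are sigmoidal
with ranges 0.37-3.15 ms and 0.37-2.22 ms, and the M-current gate is
uniformly slow, $\tau_z = 75$ ms, which is what produces adaptation.
Defaults: $g_{Na} = 24$, $g_{Kd} = 3$, $g_L = 0.02$ mS/cm^2, $E_{Na} =
55$, $E_K = -90$, $E_L = -60$ mV.

The single modulation knob is $g_{Ks}$: `0` mS/cm^2 models full
muscarinic blockade (Type I), `1.5` the unmodulated M-current (Type II).
With these values the model reproduces the textbook signatures, which
the test suite checks directly:

- Type I fires spontaneously at $I_{app} = 0$ (about 15 Hz) and is
  silenced by $-0.2$ uA/cm^2; its I-F curve rises continuously from
  onset rates below 5 Hz.
- Type II switches on at a minimum rate near 7 Hz.
- The Type I PRC is non-negative (up to a ~0.007 dip when the pulse
  lands on the spike downstroke itself); the Type II PRC has a genuine
  negative lobe for pulses early in the cycle.

## PRC protocol

The PRC is measured with the community-standard first-order protocol: the
cell is driven to periodic firing, a square pulse of 0.5 ms x 2 uA/cm^2
(about 1 mV of added charge) is delivered at 50 evenly spaced phases, and
the normalized shift $(T_0 - T_{pert})/T_0$ of the perturbed cycle is
recorded.  The amplitude was chosen so the peak advance is ~0.07,
comfortably in the linear regime; phases are sampled at midpoints
$(k - 1/2)/50$ so no pulse coincides exactly with a spike.

# Network construction

The reference network has 800 excitatory and 200 inhibitory cells.  Each
directed synapse class is wired independently as a Bernoulli graph:
connection probability 0.5 for E-I and I-E, 0.3 for E-E and I-I, no
self-synapses.  Conductances are varied jointly: $g_{EI} = g_{IE} =
g_{inter}$, and $g_{EE} = g_{II}/4$ (matching the 4:1 cell-count ratio).

Heterogeneity enters through the drive currents.  Excitatory drives are
drawn i.i.d. uniformly between the two currents at which an *isolated*
cell fires at 45 and 55 Hz; these endpoints are found by bisection
against the RK4-integrated single cell (tolerance 0.1 Hz, bracket
[0, 5] uA/cm^2 for Type I and [0, 10] for Type II), giving a 10 Hz
intrinsic-rate band centred on 50 Hz.  Inhibitory drives are uniform on
$[0.95 I_A, 1.05 I_A]$ with $I_A = -0.2$ uA/cm^2 for Type I interneurons
(which would otherwise fire spontaneously) and $+1.0$ for Type II
(placing them just below threshold); in both cases interneurons are
silent without excitatory input.

## Downscaling

The desk-scale preset (`scaled_config()`, 200E/50I) keeps every
probability, cell type and drive rule, and multiplies all four class
conductances by $1000/N = 4$.  The reason is that a cell's expected
synaptic input is (in-degree) x (conductance), and in Bernoulli wiring
the in-degree is proportional to the presynaptic population size; without
compensation a quarter-size network receives a quarter of the reference
inhibition and excitation, which moves every regime boundary.  With
compensation, the mean synaptic input matches the full-size network and
the published regime structure reproduces at a quarter of the cost;
input *fluctuations* are still larger by a factor ~2, one reason
synchrony values at the scaled size are not numerically identical to
full-size ones.

# Synapses and integration

Synaptic currents follow the double-exponential conductance kernel

$$I_{syn}(t) = g_{syn}\,(V - E_{syn}) \sum_i
  \left[e^{-(t-s_i)/\tau_d} - e^{-(t-s_i)/\tau_r}\right]$$

summed over all presynaptic spikes $s_i$, with $\tau_r = 0.2$ ms
everywhere, $\tau_d = 3$ ms for excitatory and $5.5$ ms for inhibitory
synapses, $E_{syn} = 0$ mV (excitatory) and $-75$ mV (inhibitory).  No
peak normalization is applied: each spike contributes a unit increment to
the kernel sum.  The sum is maintained by the mathematically equivalent
two-accumulator recursion (each accumulator decays exactly by
$e^{-dt/\tau}$ per step and is incremented by 1 per presynaptic spike);
the test suite verifies the recursion against the explicit sum to 1e-9
and re-integrates a synapse-driven cell in R against the C++ engine.

Integration is classical fixed-step RK4 at `dt = 0.05` ms.  Numerical
choices worth stating:

- **Frozen kernels within a step.**  Synaptic accumulator values are held
  at their step-start values inside the four RK4 stages (the membrane
  voltage still varies per stage).  The synaptic time constants are
  4-110x `dt`, so this is a higher-order-negligible approximation.
- **Spike detection** is an upward crossing of 0 mV with a 2 ms lockout;
  the spike time is recorded at the end of the crossing step, i.e. on
  the `dt` grid.  0 mV sits safely between threshold and the sodium
  overshoot.
- **Spike delivery** happens at the first step boundary after detection,
  so a spike's kernel is exactly $e^{-(t-s)/\tau}$ at later step starts.
- **Warmup:** spikes occurring before 100 ms are recorded in the raster
  but do not trigger synaptic current, letting initial transients decay;
  all measures use the final second only.
- **Initial conditions** per cell: $V \sim U(-62, -22)$ mV, $h, n \sim
  U(0.2, 0.8)$, $z \sim U(0.15, 0.25)$.
- **Convergence:** the suite checks fourth-order error decay on a
  subthreshold trace, 1 ms-per-spike agreement of spike times under step
  halving, and agreement with an adaptive LSODA integration to 1e-4 mV.
  On a coupled network, step-halving agreement is asserted on the first
  bursts after synapse onset: the network is chaotic, so trajectories at
  `dt` and `dt/2` inevitably decorrelate at long horizons no matter how
  accurate the integrator — early-horizon burst centers shift by well
  under 2 ms, while by the final second of a 1.5 s run they can drift by
  ~10 ms without any implication of integrator error.

An excitatory decay of 3 ms (not seconds) is the only physiologically
coherent reading for an AMPA-like synapse operating in a gamma-band
loop; a multi-second excitatory decay would make the PING cycle
impossible.

# Measures

**Synchrony.**  Each active cell's spike train is convolved with a
Gaussian kernel to give $V_i(t)$; with $\bar V(t)$ the population mean,

$$S = \frac{\langle \bar V^2\rangle - \langle \bar V\rangle^2}
 {\frac1N \sum_i \left(\langle V_i^2\rangle - \langle V_i\rangle^2\right)}$$

so $S = 1$ for identical trains and $S = O(1/\sqrt N)$ for independent
ones.  Cells silent in the window are excluded (synchrony *of active
cells*); including them as zero-variance traces would make the
denominator collapse.  The kernel width for this measure is not pinned
down by the defining formulas, so the package reuses the burst-detection
kernel ($e^{-\Delta t^2/1.6}$, i.e. $\sigma^2 = 0.8$ ms^2) for
consistency and exposes it as `kernel_sd`.

**Bursts.**  All spikes of a population are pooled and convolved with
$e^{-(t-c)^2/1.6}$; bursts are maximal intervals where this activity
trace stays at or above threshold (40 for 800 excitatory cells, 10 for
200 inhibitory cells, scaled proportionally with population size since
the trace is an extensive sum).  Burst centers are interval midpoints;
burst frequency is the reciprocal mean center-to-center interval;
"repetitive bursting" requires at least two bursts in the window.  Both
traces are sampled on a 0.1 ms grid (about $\sigma/9$), fine enough that
grid error is orders of magnitude below reported precision; the
brute-force oracle tests confirm 1e-9 agreement.

**Fixtures.**  `make_burst_raster()` (jittered spike packets with
optional Poisson background) and `make_async_raster()` (independent
Poisson trains) generate rasters with known ground truth, so the
measures are validated independently of the simulator.  They emulate
packet timing and jitter only — not membrane dynamics, refractoriness,
or rate adaptation — so passing measure tests says nothing about the
simulator itself (the simulator has its own oracle tests).

# The sweep pipeline

`run_sweep()` crosses a grid of $(g_{inter}, g_{II})$ values (E-E
following at $g_{II}/4$) with cell-type combinations, running several
independent repetitions per condition (fresh wiring, drives and initial
conditions each time; per-condition seeds are derived from the base seed
and the cell index so any cell is reproducible in isolation).  Per
condition, synchrony and active-cell counts are averaged over all
repetitions; burst frequency and width are averaged *only over
repetitions with repetitive bursting* and reported only when those form
a majority, with detection-count flags (`all`, `majority-partial`,
`minority`, `none`).  `run_ablation()` repeats a sweep with the I-E
conductance forced to zero after wiring — same seeds, so the ablation is
the only difference.

The default grid anchors are the three published raster configurations
(inter 0.00025/0.00175/0.002; I-I 0.00025/0.0005/0.015 mS/cm^2); the
full 2-D heatmap grids are user-configurable but deliberately not the
default, since a full-size five-repetition sweep is cluster-scale work.

## What the desk-scale experiments show

With the scaled preset and 3 repetitions (the problem size used
throughout the test suite; a single 1.5 s simulation takes a few
seconds):

- **Inter-dominant regime** (inter 0.00175, I-I 0.00025): excitatory
  bursting in every cell-type combination — the PING mechanism needs no
  particular cellular propensity for synchrony.
- **Intra-dominant regime** (inter 0.00025, I-I 0.0005): Type I
  excitatory networks show no repetitive excitatory bursting (burst
  frequency reported absent), while Type II excitatory networks burst
  through mutual excitation — here the cellular (cholinergic) state
  decides.
- **Ablation:** removing I-E synapses abolishes excitatory bursting in
  Type I excitatory inter-dominant networks (their synchrony was
  inhibition-made) but Type II excitatory networks with moderate
  intra-connectivity keep bursting without any inhibitory feedback.

# Limitations

- Single-compartment neurons; no channel noise, synaptic delays,
  plasticity, or nicotinic/synaptic ACh effects — the modulation model
  is M-current blockade only.
- The scaled preset preserves mean synaptic input but not input
  variance; quantitative synchrony values are size-dependent even though
  the regime structure is robust.
- Spike times are quantized to the integration step, bounding PRC shift
  resolution at $dt/T_0 \approx 0.002$.
- Burst-detection thresholds below ~2x the background trace level lose
  specificity; the proportional threshold scaling for non-reference
  sizes is an extrapolation.

# Worked example

```{r}
library(pingnet)

net <- build_network(scaled_config(exc_type = "I", inh_type = "I",
                                   g_inter = 0.00175, g_II = 0.00025,
                                   seed = 11))
ras <- run_simulation(net, simulation_settings(seed = 12))
measure_report(ras)

grid <- sweep_grid(inter = c(0.00025, 0.00175), intra = c(0.00025, 0.0005),
                   repetitions = 3, base_seed = 1)
res <- run_sweep(grid, progress = TRUE)
res$cells
export_heatmaps(res, "sweep_out")
```
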