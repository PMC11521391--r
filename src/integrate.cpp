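// Fixed-step RK4 integrators for the M-current pyramidal-cell model and
// for E-I networks of such cells coupled by double-exponential synapses.
//
// Membrane equation (Cm = 1 uF/cm^2, so dV/dt is in mV/ms):
//   dV/dt = -gNa*minf(V)^3*h*(V-ENa) - gKd*n^4*(V-EK) - gKs*z*(V-EK)
//           - gL*(V-EL) + Iapp - Isyn
//   dX/dt = (Xinf(V) - X)/tauX(V),  X in {h, n, z}
// The fast sodium activation m is instantaneous (m = minf(V)).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double m_inf(double V) { return 1.0 / (1.0 + exp((-V - 30.0) / 9.5)); }
static inline double h_inf(double V) { return 1.0 / (1.0 + exp((V + 53.0) / 7.0)); }
static inline double n_inf(double V) { return 1.0 / (1.0 + exp((-V - 30.0) / 10.0)); }
static inline double z_inf(double V) { return 1.0 / (1.0 + exp((-V - 39.0) / 5.0)); }
static inline double tau_h(double V) { return 0.37 + 2.78 / (1.0 + exp((V + 40.5) / 6.0)); }
static inline double tau_n(double V) { return 0.37 + 1.85 / (1.0 + exp((V + 27.0) / 15.0)); }
static const double TAU_Z = 75.0;
static const double REFRACT_MS = 2.0;  // spike-detector lockout

struct CellParams {
  double gNa, gKd, gKs, gL, ENa, EK, EL;
};

static CellParams unpack_params(const NumericVector& p) {
  CellParams cp;
  cp.gNa = p["gNa"]; cp.gKd = p["gKd"]; cp.gKs = p["gKs"]; cp.gL = p["gL"];
  cp.ENa = p["ENa"]; cp.EK = p["EK"]; cp.EL = p["EL"];
  return cp;
}

// Time-derivatives of (V, h, n, z).  gexc/ginh are the *effective* synaptic
// conductances (class conductance times summed kernel), frozen within a step.
static inline void deriv(const CellParams& p, double V, double h, double n, double z,
                         double Iext, double gexc, double ginh,
                         double EsynE, double EsynI,
                         double& dV, double& dh, double& dn, double& dz) {
  double m = m_inf(V);
  double Isyn = gexc * (V - EsynE) + ginh * (V - EsynI);
  dV = -p.gNa * m * m * m * h * (V - p.ENa)
       - p.gKd * n * n * n * n * (V - p.EK)
       - p.gKs * z * (V - p.EK)
       - p.gL * (V - p.EL)
       + Iext - Isyn;
  dh = (h_inf(V) - h) / tau_h(V);
  dn = (n_inf(V) - n) / tau_n(V);
  dz = (z_inf(V) - z) / TAU_Z;
}

// One classical RK4 step for a single cell; synaptic kernels and Iext are
// held at their step-start values (synaptic and drive timescales >> dt).
static inline void rk4_step(const CellParams& p, double dt,
                            double& V, double& h, double& n, double& z,
                            double Iext, double gexc, double ginh,
                            double EsynE, double EsynI) {
  double k1V, k1h, k1n, k1z, k2V, k2h, k2n, k2z;
  double k3V, k3h, k3n, k3z, k4V, k4h, k4n, k4z;
  deriv(p, V, h, n, z, Iext, gexc, ginh, EsynE, EsynI, k1V, k1h, k1n, k1z);
  deriv(p, V + 0.5 * dt * k1V, h + 0.5 * dt * k1h, n + 0.5 * dt * k1n, z + 0.5 * dt * k1z,
        Iext, gexc, ginh, EsynE, EsynI, k2V, k2h, k2n, k2z);
  deriv(p, V + 0.5 * dt * k2V, h + 0.5 * dt * k2h, n + 0.5 * dt * k2n, z + 0.5 * dt * k2z,
        Iext, gexc, ginh, EsynE, EsynI, k3V, k3h, k3n, k3z);
  deriv(p, V + dt * k3V, h + dt * k3h, n + dt * k3n, z + dt * k3z,
        Iext, gexc, ginh, EsynE, EsynI, k4V, k4h, k4n, k4z);
  V += dt / 6.0 * (k1V + 2.0 * k2V + 2.0 * k3V + k4V);
  h += dt / 6.0 * (k1h + 2.0 * k2h + 2.0 * k3h + k4h);
  n += dt / 6.0 * (k1n + 2.0 * k2n + 2.0 * k3n + k4n);
  z += dt / 6.0 * (k1z + 2.0 * k2z + 2.0 * k3z + k4z);
}

// [[Rcpp::export(name = ".gate_steady_cpp")]]
NumericMatrix gate_steady_cpp(NumericVector V) {
  int n = V.size();
  NumericMatrix out(n, 4);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = m_inf(V[i]);
    out(i, 1) = h_inf(V[i]);
    out(i, 2) = n_inf(V[i]);
    out(i, 3) = z_inf(V[i]);
  }
  colnames(out) = CharacterVector::create("m", "h", "n", "z");
  return out;
}

// [[Rcpp::export(name = ".gate_tau_cpp")]]
NumericMatrix gate_tau_cpp(NumericVector V) {
  int n = V.size();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = tau_h(V[i]);
    out(i, 1) = tau_n(V[i]);
    out(i, 2) = TAU_Z;
  }
  colnames(out) = CharacterVector::create("h", "n", "z");
  return out;
}

// [[Rcpp::export(name = ".deriv_cpp")]]
NumericVector deriv_cpp(NumericVector state, NumericVector params,
                        double Iapp, double Isyn) {
  CellParams p = unpack_params(params);
  double V = state[0], h = state[1], n = state[2], z = state[3];
  // express Isyn as a pure current: gexc = 0, ginh = 0, fold into Iext
  double dV, dh, dn, dz;
  deriv(p, V, h, n, z, Iapp - Isyn, 0.0, 0.0, 0.0, 0.0, dV, dh, dn, dz);
  NumericVector out = NumericVector::create(
    _["V"] = dV, _["h"] = dh, _["n"] = dn, _["z"] = dz);
  return out;
}

// Single-neuron integrator with optional square current pulse (for PRCs).
// [[Rcpp::export(name = ".sim_neuron_cpp")]]
List sim_neuron_cpp(NumericVector params, double Iapp,
                    double duration, double dt,
                    NumericVector init,
                    double pulse_start, double pulse_duration, double pulse_amp,
                    bool record_trace) {
  CellParams p = unpack_params(params);
  double V = init[0], h = init[1], n = init[2], z = init[3];
  int nsteps = (int)std::floor(duration / dt + 0.5);
  std::vector<double> spikes;
  std::vector<double> trace, trh, trn, trz;
  if (record_trace) {
    trace.reserve(nsteps + 1); trh.reserve(nsteps + 1);
    trn.reserve(nsteps + 1); trz.reserve(nsteps + 1);
    trace.push_back(V); trh.push_back(h); trn.push_back(n); trz.push_back(z);
  }
  double last_spike = -1e9;
  bool ok = true;
  int bad_step = -1;
  for (int k = 0; k < nsteps; ++k) {
    double t = k * dt;
    double Iext = Iapp;
    if (pulse_duration > 0.0 && t >= pulse_start && t < pulse_start + pulse_duration)
      Iext += pulse_amp;
    double Vprev = V;
    rk4_step(p, dt, V, h, n, z, Iext, 0.0, 0.0, 0.0, 0.0);
    if (!std::isfinite(V) || !std::isfinite(h) || !std::isfinite(n) || !std::isfinite(z)) {
      ok = false; bad_step = k; break;
    }
    double tnew = (k + 1) * dt;
    if (Vprev < 0.0 && V >= 0.0 && tnew - last_spike >= REFRACT_MS) {
      spikes.push_back(tnew);
      last_spike = tnew;
    }
    if (record_trace) {
      trace.push_back(V); trh.push_back(h); trn.push_back(n); trz.push_back(z);
    }
  }
  List out = List::create(
    _["spikes"] = wrap(spikes),
    _["state"] = NumericVector::create(_["V"] = V, _["h"] = h, _["n"] = n, _["z"] = z),
    _["ok"] = ok,
    _["bad_step"] = bad_step);
  if (record_trace) {
    out["V"] = wrap(trace); out["h"] = wrap(trh);
    out["n"] = wrap(trn); out["z"] = wrap(trz);
  }
  return out;
}

// Network integrator.  Cells 0..n_exc-1 are excitatory, the rest inhibitory.
// Adjacency is CSR by presynaptic cell with absolute 0-based target indices:
// exc_ptr/exc_idx give targets of each excitatory cell (E->E and E->I edges
// merged: both feed the excitatory-kernel accumulators of the target),
// inh_ptr/inh_idx likewise for inhibitory cells.  Each target cell keeps one
// rise/decay accumulator pair per incoming synapse class; the class
// conductance applied is determined by the (pre, post) populations.
// [[Rcpp::export(name = ".sim_network_cpp")]]
List sim_network_cpp(int n_exc, int n_inh,
                     NumericVector params_exc, NumericVector params_inh,
                     NumericVector Iapp, NumericMatrix init,
                     IntegerVector exc_ptr, IntegerVector exc_idx,
                     IntegerVector inh_ptr, IntegerVector inh_idx,
                     double gEE, double gEI, double gIE, double gII,
                     double duration, double dt, double synapse_onset,
                     double tau_r, double tau_d_exc, double tau_d_inh,
                     double Esyn_exc, double Esyn_inh,
                     IntegerVector record_idx) {
  int N = n_exc + n_inh;
  CellParams pe = unpack_params(params_exc);
  CellParams pi = unpack_params(params_inh);
  std::vector<double> V(N), h(N), n(N), z(N);
  for (int i = 0; i < N; ++i) {
    V[i] = init(i, 0); h[i] = init(i, 1); n[i] = init(i, 2); z[i] = init(i, 3);
  }
  // accumulators: excitatory-kernel (d, r) and inhibitory-kernel (d, r)
  std::vector<double> Aed(N, 0.0), Aer(N, 0.0), Aid(N, 0.0), Air(N, 0.0);
  double dec_r = exp(-dt / tau_r);
  double dec_de = exp(-dt / tau_d_exc);
  double dec_di = exp(-dt / tau_d_inh);
  int nsteps = (int)std::floor(duration / dt + 0.5);
  std::vector< std::vector<double> > spikes(N);
  std::vector<double> last_spike(N, -1e9);
  std::vector<int> spikers;
  spikers.reserve(N);
  int nrec = record_idx.size();
  NumericMatrix traces(nrec > 0 ? nsteps + 1 : 0, nrec);
  for (int r = 0; r < nrec; ++r) traces(0, r) = V[record_idx[r]];
  bool ok = true;
  int bad_step = -1, bad_cell = -1;
  for (int k = 0; k < nsteps && ok; ++k) {
    double tnew = (k + 1) * dt;
    spikers.clear();
    for (int i = 0; i < N; ++i) {
      bool is_exc = i < n_exc;
      const CellParams& p = is_exc ? pe : pi;
      double gexc = (is_exc ? gEE : gEI) * (Aed[i] - Aer[i]);
      double ginh = (is_exc ? gIE : gII) * (Aid[i] - Air[i]);
      double Vprev = V[i];
      rk4_step(p, dt, V[i], h[i], n[i], z[i], Iapp[i], gexc, ginh,
               Esyn_exc, Esyn_inh);
      if (!std::isfinite(V[i])) {
        ok = false; bad_step = k; bad_cell = i; break;
      }
      if (Vprev < 0.0 && V[i] >= 0.0 && tnew - last_spike[i] >= REFRACT_MS) {
        spikes[i].push_back(tnew);
        last_spike[i] = tnew;
        spikers.push_back(i);
      }
    }
    if (!ok) break;
    // decay accumulators to t + dt, then deliver this step's spikes so the
    // kernel of a spike at s evaluates to exp(-(t-s)/tau) at later steps
    for (int i = 0; i < N; ++i) {
      Aed[i] *= dec_de; Aer[i] *= dec_r;
      Aid[i] *= dec_di; Air[i] *= dec_r;
    }
    if (tnew >= synapse_onset) {
      for (size_t s = 0; s < spikers.size(); ++s) {
        int pre = spikers[s];
        if (pre < n_exc) {
          for (int e = exc_ptr[pre]; e < exc_ptr[pre + 1]; ++e) {
            int post = exc_idx[e];
            Aed[post] += 1.0; Aer[post] += 1.0;
          }
        } else {
          int pre_i = pre - n_exc;
          for (int e = inh_ptr[pre_i]; e < inh_ptr[pre_i + 1]; ++e) {
            int post = inh_idx[e];
            Aid[post] += 1.0; Air[post] += 1.0;
          }
        }
      }
    }
    for (int r = 0; r < nrec; ++r) traces(k + 1, r) = V[record_idx[r]];
  }
  List spk(N);
  for (int i = 0; i < N; ++i) spk[i] = wrap(spikes[i]);
  List out = List::create(
    _["spikes"] = spk,
    _["ok"] = ok,
    _["bad_step"] = bad_step,
    _["bad_cell"] = bad_cell);
  if (nrec > 0) out["traces"] = traces;
  return out;
}
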