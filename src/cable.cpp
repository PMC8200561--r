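// Compartmental cable integrator for branched fibers.
//
// Semi-implicit scheme: gating variables advance by the exact exponential
// update at the current voltage; the membrane equation is then linear in
// V(t+dt) (channel conductances, leak, synaptic conductances and axial
// coupling all treated implicitly) and solved directly on the tree with the
// Hines ordering (parent index < child index).
//
// Units: mV, ms, nF, uS, nA.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

constexpr double V_TAB_MIN = -150.0;
constexpr double V_TAB_MAX = 80.0;
constexpr double V_TAB_STEP = 0.05;

struct GateTable {
  std::vector<double> inf;
  std::vector<double> expfac; // exp(-dt / tau(V)) for the fixed dt of the run
};

inline int tab_size() {
  return static_cast<int>((V_TAB_MAX - V_TAB_MIN) / V_TAB_STEP) + 1;
}

inline double tab_lookup(const std::vector<double>& t, double v) {
  double x = (v - V_TAB_MIN) / V_TAB_STEP;
  if (x <= 0) return t.front();
  int n = static_cast<int>(t.size());
  if (x >= n - 1) return t.back();
  int i = static_cast<int>(x);
  double f = x - i;
  return t[i] * (1 - f) + t[i + 1] * f;
}

inline double ipow(double x, int p) {
  double r = 1.0;
  for (int i = 0; i < p; ++i) r *= x;
  return r;
}

} // namespace

// Compartment indices are 0-based (-1 marks the root's parent). gate_types
// columns: v_half, slope_k, act, root_exp, tau_peak, tau_center, tau_width,
// tau_floor, hyper_scale. syn_g_us and stim_na have nsteps+1 rows.
// [[Rcpp::export]]
List cable_simulate_cpp(IntegerVector parent,
                        NumericVector c_nf,
                        NumericVector g_axial_us,
                        NumericVector g_leak_us,
                        NumericVector e_leak_mv,
                        IntegerVector chan_comp,
                        NumericVector chan_gbar_us,
                        NumericVector chan_erev,
                        IntegerVector chan_gate_start,
                        IntegerVector chan_ngates,
                        IntegerVector gate_type,
                        IntegerVector gate_exp,
                        NumericVector gate_x0,
                        DataFrame gate_types,
                        IntegerVector syn_comp,
                        NumericMatrix syn_g_us,
                        NumericVector syn_erev,
                        IntegerVector stim_comp,
                        NumericMatrix stim_na,
                        double dt, int nsteps, double v_init,
                        IntegerVector record,
                        int record_every) {
  const int ncomp = parent.size();
  const int nchan = chan_comp.size();
  (void)gate_type;
  const int nsyn = syn_comp.size();
  const int nstim = stim_comp.size();
  const int ntype = gate_types.nrows();

  NumericVector ty_vh = gate_types["v_half"], ty_k = gate_types["slope_k"],
                ty_act = gate_types["act"], ty_root = gate_types["root_exp"],
                ty_pk = gate_types["tau_peak"], ty_ce = gate_types["tau_center"],
                ty_wd = gate_types["tau_width"], ty_fl = gate_types["tau_floor"],
                ty_hs = gate_types["hyper_scale"];

  // build lookup tables for this dt
  const int nt = tab_size();
  std::vector<GateTable> tab(ntype);
  for (int k = 0; k < ntype; ++k) {
    tab[k].inf.resize(nt);
    tab[k].expfac.resize(nt);
    double sgn = ty_act[k] > 0.5 ? -1.0 : 1.0;
    for (int i = 0; i < nt; ++i) {
      double v = V_TAB_MIN + i * V_TAB_STEP;
      double b = 1.0 / (1.0 + std::exp(sgn * (v - ty_vh[k]) / ty_k[k]));
      if (ty_root[k] > 1.5) b = std::pow(b, 1.0 / ty_root[k]);
      double z = (v - ty_ce[k]) / ty_wd[k];
      double tau = ty_fl[k] + (ty_pk[k] - ty_fl[k]) * std::exp(-z * z);
      if (ty_hs[k] != 1.0 && v < ty_ce[k]) tau *= ty_hs[k];
      tab[k].inf[i] = b;
      tab[k].expfac[i] = std::exp(-dt / tau);
    }
  }

  std::vector<double> v(ncomp, v_init), x(gate_x0.begin(), gate_x0.end());
  std::vector<double> diag(ncomp), rhs(ncomp), cdt(ncomp);
  for (int i = 0; i < ncomp; ++i) cdt[i] = c_nf[i] / dt;

  const int nrec = record.size();
  const int nsamp = nsteps / record_every + 1;
  NumericMatrix trace(nsamp, nrec);
  NumericVector vmax(ncomp, v_init);
  for (int r = 0; r < nrec; ++r) trace(0, r) = v_init;

  for (int step = 1; step <= nsteps; ++step) {
    // 1. gate update at current voltages
    for (int c = 0; c < nchan; ++c) {
      double vc = v[chan_comp[c]];
      int g0 = chan_gate_start[c], gn = chan_ngates[c];
      for (int g = g0; g < g0 + gn; ++g) {
        const GateTable& T = tab[gate_type[g]];
        double inf = tab_lookup(T.inf, vc);
        double f = tab_lookup(T.expfac, vc);
        x[g] = inf + (x[g] - inf) * f;
      }
    }
    // 2. assemble linear system
    for (int i = 0; i < ncomp; ++i) {
      diag[i] = cdt[i] + g_leak_us[i];
      rhs[i] = cdt[i] * v[i] + g_leak_us[i] * e_leak_mv[i];
    }
    for (int c = 0; c < nchan; ++c) {
      double open = 1.0;
      int g0 = chan_gate_start[c], gn = chan_ngates[c];
      for (int g = g0; g < g0 + gn; ++g) open *= ipow(x[g], gate_exp[g]);
      double gc = chan_gbar_us[c] * open;
      int i = chan_comp[c];
      diag[i] += gc;
      rhs[i] += gc * chan_erev[c];
    }
    for (int s = 0; s < nsyn; ++s) {
      double gs = syn_g_us(step, s);
      int i = syn_comp[s];
      diag[i] += gs;
      rhs[i] += gs * syn_erev[s];
    }
    for (int s = 0; s < nstim; ++s) rhs[stim_comp[s]] += stim_na(step, s);
    // axial coupling (implicit, symmetric)
    for (int i = 1; i < ncomp; ++i) {
      double ga = g_axial_us[i];
      diag[i] += ga;
      diag[parent[i]] += ga;
    }
    // 3. Hines solve
    for (int i = ncomp - 1; i >= 1; --i) {
      double ga = g_axial_us[i];
      double f = ga / diag[i];
      diag[parent[i]] -= ga * f;
      rhs[parent[i]] += rhs[i] * f;
    }
    v[0] = rhs[0] / diag[0];
    for (int i = 1; i < ncomp; ++i)
      v[i] = (rhs[i] + g_axial_us[i] * v[parent[i]]) / diag[i];
    // 4. sanity + record
    for (int i = 0; i < ncomp; ++i) {
      if (!std::isfinite(v[i]) || std::fabs(v[i]) > 200.0)
        stop("Numerical failure: |V| > 200 mV in compartment %d at t = %.3f ms",
             i + 1, step * dt);
      if (v[i] > vmax[i]) vmax[i] = v[i];
    }
    if (step % record_every == 0) {
      int row = step / record_every;
      for (int r = 0; r < nrec; ++r) trace(row, r) = v[record[r]];
    }
  }

  return List::create(_["trace"] = trace, _["v_max"] = vmax,
                      _["gate_final"] = NumericVector(x.begin(), x.end()));
}
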