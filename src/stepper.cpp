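// Backward-Euler integration of the discretized cable system on a tree.
//
// Units: mV, ms, uS, nF, nA. The voltage system is solved implicitly each
// step with a Hines (tree-ordered) elimination; gating variables advance by
// the exact exponential update at the voltage of the previous step. The
// uniform extracellular field enters as a per-compartment source current
// E * sum_adj g_ax * (vext_unit_adj - vext_unit_self), the discrete
// activating-function form of coupling through extracellular potential
// differences.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct GateDef {
  int channel;
  double power;
  double vhalf, k;
  int tau_type;           // 0 constant, 1 bell
  double p0, p1, p2, p3, p4; // tau0 | min, amp, vmax, k1, k2
};

inline double gate_inf(const GateDef &g, double v) {
  return 1.0 / (1.0 + std::exp((g.vhalf - v) / g.k));
}

inline double gate_tau(const GateDef &g, double v) {
  if (g.tau_type == 0) return g.p0;
  return g.p0 + g.p1 / (std::exp((v - g.p2) / g.p3) + std::exp(-(v - g.p2) / g.p4));
}

const double TAB_VMIN = -150.0, TAB_VMAX = 80.0, TAB_DV = 0.05;

} // namespace

// [[Rcpp::export]]
List cpp_simulate(IntegerVector parent, NumericVector g_axial,
                  NumericVector cm, NumericVector gleak, double eleak,
                  NumericMatrix gbar, NumericVector erev,
                  IntegerVector gate_channel, NumericVector gate_power,
                  NumericVector gate_vhalf, NumericVector gate_k,
                  IntegerVector tau_type, NumericMatrix tau_params,
                  NumericVector vext_unit, double e_amp, double e_on, double e_off,
                  IntegerVector inj_comp, NumericVector inj_amp,
                  NumericVector inj_on, NumericVector inj_off,
                  double dt, int nsteps,
                  NumericVector v0, NumericMatrix gates0,
                  IntegerVector record_idx, int record_stride,
                  bool use_tables, bool track_residual) {
  const int n = parent.size();
  const int nchan = erev.size();
  const int ngate = gate_channel.size();
  const int nrec = record_idx.size();

  std::vector<GateDef> gates(ngate);
  for (int g = 0; g < ngate; ++g) {
    gates[g].channel = gate_channel[g];
    gates[g].power = gate_power[g];
    gates[g].vhalf = gate_vhalf[g];
    gates[g].k = gate_k[g];
    gates[g].tau_type = tau_type[g];
    gates[g].p0 = tau_params(g, 0); gates[g].p1 = tau_params(g, 1);
    gates[g].p2 = tau_params(g, 2); gates[g].p3 = tau_params(g, 3);
    gates[g].p4 = tau_params(g, 4);
  }

  // rate tables: inf and exp(-dt/tau) on a voltage grid
  int ntab = 0;
  std::vector<double> tab_inf, tab_fac;
  if (use_tables && ngate > 0) {
    ntab = (int)std::floor((TAB_VMAX - TAB_VMIN) / TAB_DV) + 1;
    tab_inf.resize((size_t)ngate * ntab);
    tab_fac.resize((size_t)ngate * ntab);
    for (int g = 0; g < ngate; ++g) {
      for (int t = 0; t < ntab; ++t) {
        double v = TAB_VMIN + t * TAB_DV;
        tab_inf[(size_t)g * ntab + t] = gate_inf(gates[g], v);
        tab_fac[(size_t)g * ntab + t] = std::exp(-dt / gate_tau(gates[g], v));
      }
    }
  }

  // static topology quantities
  std::vector<double> gax_sum(n, 0.0), fsrc(n, 0.0);
  for (int i = 0; i < n; ++i) {
    int p = parent[i];
    if (p >= 0) {
      gax_sum[i] += g_axial[i];
      gax_sum[p] += g_axial[i];
      double dv = vext_unit[p] - vext_unit[i];
      fsrc[i] += g_axial[i] * dv;
      fsrc[p] -= g_axial[i] * dv;
    }
  }

  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> x((size_t)n * ngate);
  for (int i = 0; i < n; ++i)
    for (int g = 0; g < ngate; ++g) x[(size_t)i * ngate + g] = gates0(i, g);

  int nrec_t = nsteps / record_stride + 1;
  NumericMatrix vrec(nrec_t, nrec);
  NumericVector times(nrec_t);
  int rec_row = 0;
  for (int s = 0; s < nrec; ++s) vrec(0, s) = v[record_idx[s]];
  times[0] = 0.0;
  rec_row = 1;

  std::vector<double> d(n), b(n), open(nchan), d0, b0;
  if (track_residual) { d0.resize(n); b0.resize(n); }
  double max_resid = 0.0;
  double vmax_all = R_NegInf;
  bool diverged = false;
  double div_time = NA_REAL;
  int div_comp = -1;
  const int ninj = inj_comp.size();

  for (int step = 1; step <= nsteps; ++step) {
    double t1 = step * dt;
    bool field_on = (e_amp != 0.0) && (t1 > e_on) && (t1 <= e_off);

    // gating update at frozen V (previous step), exact exponential
    if (ngate > 0) {
      for (int i = 0; i < n; ++i) {
        double vi = v[i];
        if (use_tables) {
          double vc = vi < TAB_VMIN ? TAB_VMIN : (vi > TAB_VMAX ? TAB_VMAX : vi);
          double pos = (vc - TAB_VMIN) / TAB_DV;
          int t0 = (int)pos; if (t0 >= ntab - 1) t0 = ntab - 2;
          double w = pos - t0;
          for (int g = 0; g < ngate; ++g) {
            size_t base = (size_t)g * ntab + t0;
            double inf = tab_inf[base] * (1 - w) + tab_inf[base + 1] * w;
            double fac = tab_fac[base] * (1 - w) + tab_fac[base + 1] * w;
            size_t idx = (size_t)i * ngate + g;
            x[idx] = inf + (x[idx] - inf) * fac;
          }
        } else {
          for (int g = 0; g < ngate; ++g) {
            double inf = gate_inf(gates[g], vi);
            double fac = std::exp(-dt / gate_tau(gates[g], vi));
            size_t idx = (size_t)i * ngate + g;
            x[idx] = inf + (x[idx] - inf) * fac;
          }
        }
      }
    }

    // assemble diagonal and rhs
    for (int i = 0; i < n; ++i) {
      double gtot = gleak[i];
      double gE = gleak[i] * eleak;
      if (nchan > 0) {
        for (int c = 0; c < nchan; ++c) open[c] = 1.0;
        for (int g = 0; g < ngate; ++g) {
          double xv = x[(size_t)i * ngate + g];
          double p = gates[g].power;
          double xp;
          if (p == 1.0) xp = xv;
          else if (p == 2.0) xp = xv * xv;
          else if (p == 3.0) xp = xv * xv * xv;
          else if (p == 4.0) { double x2 = xv * xv; xp = x2 * x2; }
          else xp = std::pow(xv, p);
          open[gates[g].channel] *= xp;
        }
        for (int c = 0; c < nchan; ++c) {
          double gc = gbar(i, c) * open[c];
          gtot += gc;
          gE += gc * erev[c];
        }
      }
      d[i] = cm[i] / dt + gtot + gax_sum[i];
      b[i] = cm[i] / dt * v[i] + gE;
      if (field_on) b[i] += e_amp * fsrc[i];
    }
    for (int j = 0; j < ninj; ++j) {
      if (t1 > inj_on[j] && t1 <= inj_off[j]) b[inj_comp[j]] += inj_amp[j];
    }

    if (track_residual) { d0 = d; b0 = b; }

    // Hines elimination (children before parents; parent[i] < i holds)
    for (int i = n - 1; i >= 1; --i) {
      int p = parent[i];
      double f = g_axial[i] / d[i];
      d[p] -= f * g_axial[i];
      b[p] += f * b[i];
    }
    v[0] = b[0] / d[0];
    for (int i = 1; i < n; ++i) v[i] = (b[i] + g_axial[i] * v[parent[i]]) / d[i];

    if (track_residual) {
      // residual of the assembled linear system: at every node the implicit
      // membrane + capacitive current balances the signed axial currents
      for (int i = 0; i < n; ++i) {
        double ax = 0.0, axmax = 0.0;
        int p = parent[i];
        if (p >= 0) { double t = g_axial[i] * v[p]; ax += t; axmax = std::max(axmax, std::fabs(t)); }
        // children terms
        // (scan is O(n^2) worst case but n is small; children are i2 with parent == i)
        for (int i2 = i + 1; i2 < n; ++i2) {
          if (parent[i2] == i) {
            double t = g_axial[i2] * v[i2];
            ax += t; axmax = std::max(axmax, std::fabs(t));
          }
        }
        double lhs = d0[i] * v[i];
        double r = lhs - ax - b0[i];
        double denom = std::max({std::fabs(lhs), std::fabs(b0[i]), axmax, 1e-300});
        double rel = std::fabs(r) / denom;
        if (rel > max_resid) max_resid = rel;
      }
    }

    for (int i = 0; i < n; ++i) {
      if (v[i] > vmax_all) vmax_all = v[i];
      if (!(std::fabs(v[i]) <= 500.0)) {
        diverged = true; div_time = t1; div_comp = i;
        break;
      }
    }
    if (diverged) break;

    if (step % record_stride == 0) {
      for (int s = 0; s < nrec; ++s) vrec(rec_row, s) = v[record_idx[s]];
      times[rec_row] = t1;
      ++rec_row;
    }
  }

  if (rec_row < nrec_t) {
    vrec = vrec(Range(0, std::max(rec_row - 1, 0)), Range(0, std::max(nrec - 1, 0)));
    times = times[Range(0, std::max(rec_row - 1, 0))];
  }

  NumericVector vfin(n);
  for (int i = 0; i < n; ++i) vfin[i] = v[i];
  NumericMatrix gfin(n, ngate);
  for (int i = 0; i < n; ++i)
    for (int g = 0; g < ngate; ++g) gfin(i, g) = x[(size_t)i * ngate + g];

  return List::create(_["times"] = times, _["v"] = vrec,
                      _["v_final"] = vfin, _["gates_final"] = gfin,
                      _["max_residual"] = max_resid,
                      _["v_max"] = vmax_all,
                      _["diverged"] = diverged,
                      _["diverge_time"] = div_time,
                      _["diverge_comp"] = div_comp + 1);
}
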