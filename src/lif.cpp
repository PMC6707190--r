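#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Core integrator for the adapting leaky integrate-and-fire network.
//
// Subthreshold dynamics per neuron i:
//   dv_i/dt = f_i(t) + s_i(t) - v_i/tau_m - gamma * a_i(t)
//   ds_i/dt = -s_i/tau_s + sum_j w_ij delta(t - t_spike^j)
//   da_i/dt = -a_i/tau_a + delta(t - t_spike^i)
// with reset v -> v - theta when v >= theta.
//
// Voltage is advanced with a two-stage (Heun / modified Euler) step; the
// exponentially decaying traces s and a are advanced exactly. A threshold
// crossing within a step is timed by linear interpolation between the step
// endpoint voltages; the reset and all spike-triggered increments are applied
// at the end of the step. Postsynaptic increments are optionally weighted by
// exp(-(t_end - t_spike)/tau_s) so the synaptic trace at the step boundary is
// first-order consistent with the interpolated spike time.
//
// Connectivity is CSC by presynaptic neuron: targets of neuron j are
// syn_i[syn_p[j] .. syn_p[j+1]-1] with weights syn_x (0-based indices).
// Drive is a (n_groups x n_cols) matrix sampled on the integration grid;
// n_cols == 1 means time-constant drive, otherwise n_cols must be
// n_steps + 1 and column k holds the drive at time k*h.

// [[Rcpp::export]]
List lif_run_cpp(NumericVector v0,
                 IntegerVector syn_p, IntegerVector syn_i, NumericVector syn_x,
                 double theta, double tau_m, double tau_s, double tau_a,
                 double gamma, double h,
                 NumericMatrix drive, IntegerVector group,
                 int n_steps, bool sync_weighted,
                 NumericVector s0, NumericVector a0) {
  const int n = v0.size();
  if (h <= 0) stop("integration step h must be positive");
  if (group.size() != n) stop("group must have one entry per neuron");
  const int ngrp = drive.nrow();
  const int ncol = drive.ncol();
  const bool const_drive = (ncol == 1);
  if (!const_drive && ncol != n_steps + 1)
    stop("drive trace is shorter than the simulation (%d columns, need %d)",
         ncol, n_steps + 1);

  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> s(s0.begin(), s0.end());
  std::vector<double> a(a0.begin(), a0.end());
  std::vector<double> vold(n);
  const double es = std::exp(-h / tau_s);
  const double ea = std::exp(-h / tau_a);
  const double itm = 1.0 / tau_m;
  const double hh = 0.5 * h;
  const double *dptr = REAL(drive);
  const int *grp = INTEGER(group);

  std::vector<int> spk_id;
  std::vector<double> spk_t;
  std::vector<int> spikers;
  spikers.reserve(256);

  for (int k = 0; k < n_steps; ++k) {
    if ((k & 16383) == 0) checkUserInterrupt();
    const double t = k * h;
    const double *f1 = dptr + (const_drive ? 0 : (size_t)k * ngrp);
    const double *f2 = dptr + (const_drive ? 0 : (size_t)(k + 1) * ngrp);
    spikers.clear();
    for (int i = 0; i < n; ++i) {
      const int g = grp[i];
      const double vi = v[i];
      const double g1 = f1[g] + s[i] - vi * itm - gamma * a[i];
      const double s2 = s[i] * es;
      const double a2 = a[i] * ea;
      const double vp = vi + h * g1;
      const double g2 = f2[g] + s2 - vp * itm - gamma * a2;
      const double vn = vi + hh * (g1 + g2);
      if (!std::isfinite(vn))
        stop("non-finite voltage for neuron %d at t = %.3f ms", i + 1, t + h);
      vold[i] = vi;
      v[i] = vn;
      s[i] = s2;
      a[i] = a2;
      if (vn >= theta) spikers.push_back(i);
    }
    for (size_t m = 0; m < spikers.size(); ++m) {
      const int i = spikers[m];
      double frac = (theta - vold[i]) / (v[i] - vold[i]);
      if (!(frac >= 0.0)) frac = 0.0;
      if (frac > 1.0) frac = 1.0;
      spk_id.push_back(i + 1);
      spk_t.push_back(t + frac * h);
      v[i] -= theta;
      a[i] += 1.0;
      const double wfac =
          sync_weighted ? std::exp(-(1.0 - frac) * h / tau_s) : 1.0;
      const int from = syn_p[i], to = syn_p[i + 1];
      for (int idx = from; idx < to; ++idx)
        s[syn_i[idx]] += syn_x[idx] * wfac;
    }
  }

  return List::create(
      _["id"] = IntegerVector(spk_id.begin(), spk_id.end()),
      _["time"] = NumericVector(spk_t.begin(), spk_t.end()),
      _["v"] = NumericVector(v.begin(), v.end()),
      _["s"] = NumericVector(s.begin(), s.end()),
      _["a"] = NumericVector(a.begin(), a.end()));
}
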