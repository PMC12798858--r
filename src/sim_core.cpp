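// Semi-implicit cable integrator for tanh-formalism Hodgkin-Huxley channels.
//
// Units (repo-wide convention): mV, ms, nS, pA, pF, um.  nS*mV = pA and
// pF*mV/ms = pA, so no conversion factors appear anywhere.
//
// Scheme: gating variables advance by exponential Euler (exact for clamped V);
// the voltage diffusion/leak system is solved implicitly each step with a
// Hines elimination over the compartment tree (parents precede children).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Gate {
  double v_half, v_slope, tau_max, tau_min, v_tau_half, v_tau_slope;
};

inline double steady(const Gate &g, double v) {
  return 0.5 + 0.5 * std::tanh((v - g.v_half) / g.v_slope);
}

inline double tau_of(const Gate &g, double v) {
  double t = std::tanh((v - g.v_tau_half) / g.v_tau_slope);
  return (g.tau_max - g.tau_min) * (1.0 - t * t) + g.tau_min;
}

inline double ipow(double x, int p) {
  double r = 1.0;
  for (int i = 0; i < p; ++i) r *= x;
  return r;
}

} // namespace

// Columns of `kin` (one row per channel type):
//  0 p, 1 E, 2 has_inact,
//  3..8  activation  (v_half, v_slope, tau_max, tau_min, v_tau_half, v_tau_slope)
//  9..14 inactivation (same order; ignored when has_inact == 0)
//
// gbar: ncomp x nchan matrix of total conductance (nS) per compartment.
// parent: 0-based parent index per compartment, -1 for the root; parents must
// precede children in the ordering. g_ax[i] couples i to parent[i] (nS).
//
// i_stim / g_syn: per-step stimulus sampled at step start (length n_steps or 0).
// Early stop: when v[record[0]] crosses `stop_v` upward, integrate a further
// `stop_after_ms` and return (NA stop_v disables).
// [[Rcpp::export]]
List sim_core(IntegerVector parent, NumericVector g_ax, NumericVector cm,
              NumericMatrix gbar, NumericMatrix kin,
              NumericVector v0, NumericMatrix m0, NumericMatrix h0,
              double dt, int n_steps,
              NumericVector i_stim, int stim_comp,
              NumericVector g_syn, int syn_comp, double e_syn,
              IntegerVector record,
              double stop_v, double stop_after_ms,
              int record_every) {
  const int n = parent.size();
  const int nchan = kin.nrow();
  const int nrec = record.size();
  if (record_every < 1) record_every = 1;

  std::vector<Gate> act(nchan), inact(nchan);
  std::vector<int> pexp(nchan), has_h(nchan);
  std::vector<double> erev(nchan);
  for (int c = 0; c < nchan; ++c) {
    pexp[c] = (int)kin(c, 0);
    erev[c] = kin(c, 1);
    has_h[c] = (int)kin(c, 2);
    act[c] = {kin(c, 3), kin(c, 4), kin(c, 5), kin(c, 6), kin(c, 7), kin(c, 8)};
    inact[c] = {kin(c, 9), kin(c, 10), kin(c, 11), kin(c, 12), kin(c, 13), kin(c, 14)};
  }

  // active (compartment, channel) pairs, gated ones separated from leak-like
  std::vector<int> pc, pch;
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < nchan; ++c)
      if (gbar(i, c) > 0.0) { pc.push_back(i); pch.push_back(c); }
  const int npair = (int)pc.size();

  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> m(npair), h(npair, 1.0);
  for (int k = 0; k < npair; ++k) {
    m[k] = m0(pc[k], pch[k]);
    if (has_h[pch[k]]) h[k] = h0(pc[k], pch[k]);
  }

  // children lists not needed: Hines uses parent pointers only
  std::vector<double> diagv(n), rhs(n), gsum(n), gesum(n);

  const int max_rec = n_steps / record_every + 2;
  NumericMatrix out(max_rec, nrec);
  NumericVector t_out(max_rec);

  bool stopping = std::isfinite(stop_v) ? false : true; // 'true' means ignore
  bool armed = std::isfinite(stop_v);
  double stop_at = -1.0;
  bool crossed = false;
  double prev_v0 = v[record[0]];
  int n_written = 0;
  int diverged_at = -1;

  // record initial state (t = 0)
  for (int r = 0; r < nrec; ++r) out(n_written, r) = v[record[r]];
  t_out[n_written] = 0.0;
  ++n_written;

  int step = 0;
  for (step = 0; step < n_steps; ++step) {
    // --- gates (exponential Euler at current V) and conductance accumulation
    std::fill(gsum.begin(), gsum.end(), 0.0);
    std::fill(gesum.begin(), gesum.end(), 0.0);
    for (int k = 0; k < npair; ++k) {
      const int i = pc[k], c = pch[k];
      double gv = gbar(i, c);
      if (pexp[c] > 0) {
        const double minf = steady(act[c], v[i]);
        const double tm = tau_of(act[c], v[i]);
        m[k] += (minf - m[k]) * (-std::expm1(-dt / tm));
        double mm = ipow(m[k], pexp[c]);
        if (has_h[c]) {
          const double hinf = steady(inact[c], v[i]);
          const double th = tau_of(inact[c], v[i]);
          h[k] += (hinf - h[k]) * (-std::expm1(-dt / th));
          mm *= h[k];
        }
        gv *= mm;
      }
      gsum[i] += gv;
      gesum[i] += gv * erev[c];
    }

    // --- stimulus (sampled at the new time level)
    double istim_now = 0.0, gsyn_now = 0.0;
    if (i_stim.size() > 0) istim_now = i_stim[step < i_stim.size() ? step : i_stim.size() - 1];
    if (g_syn.size() > 0) gsyn_now = g_syn[step < g_syn.size() ? step : g_syn.size() - 1];

    // --- assemble implicit system  (C/dt + gsum + sum g_ax) V' - couplings = rhs
    for (int i = 0; i < n; ++i) {
      diagv[i] = cm[i] / dt + gsum[i];
      rhs[i] = cm[i] / dt * v[i] + gesum[i];
    }
    if (i_stim.size() > 0) rhs[stim_comp] += istim_now;
    if (g_syn.size() > 0 && gsyn_now != 0.0) {
      diagv[syn_comp] += gsyn_now;
      rhs[syn_comp] += gsyn_now * e_syn;
    }
    for (int i = 1; i < n; ++i) {
      const int p = parent[i];
      diagv[i] += g_ax[i];
      diagv[p] += g_ax[i];
    }
    // Hines elimination: children (higher index) into parents
    for (int i = n - 1; i >= 1; --i) {
      const int p = parent[i];
      const double f = g_ax[i] / diagv[i];
      diagv[p] -= f * g_ax[i];
      rhs[p] += f * rhs[i];
    }
    v[0] = rhs[0] / diagv[0];
    for (int i = 1; i < n; ++i)
      v[i] = (rhs[i] + g_ax[i] * v[parent[i]]) / diagv[i];

    // --- record
    if ((step + 1) % record_every == 0) {
      for (int r = 0; r < nrec; ++r) out(n_written, r) = v[record[r]];
      t_out[n_written] = (step + 1) * dt;
      ++n_written;
    }

    // --- divergence check
    if (std::abs(v[record[0]]) > 200.0 || !std::isfinite(v[record[0]])) {
      diverged_at = step;
      break;
    }

    // --- early stop
    if (armed && !crossed) {
      if (prev_v0 < stop_v && v[record[0]] >= stop_v) {
        crossed = true;
        stop_at = (step + 1) * dt + stop_after_ms;
      }
      prev_v0 = v[record[0]];
    }
    if (crossed && (step + 1) * dt >= stop_at) { ++step; break; }
  }

  // final gate state back into full matrices
  NumericMatrix mF(n, nchan), hF(n, nchan);
  std::fill(hF.begin(), hF.end(), 1.0);
  for (int k = 0; k < npair; ++k) {
    mF(pc[k], pch[k]) = m[k];
    hF(pc[k], pch[k]) = h[k];
  }

  return List::create(
      _["v"] = out(Range(0, n_written - 1), Range(0, nrec - 1)),
      _["t"] = t_out[Range(0, n_written - 1)],
      _["n_steps_done"] = step,
      _["v_final"] = NumericVector(v.begin(), v.end()),
      _["m_final"] = mF, _["h_final"] = hF,
      _["diverged_at"] = diverged_at < 0 ? R_NilValue : (SEXP)wrap(diverged_at * dt),
      _["stopped_early"] = crossed);
}
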