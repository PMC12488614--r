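// Semi-implicit cable integrator.
//
// Per step (staggered scheme): gate states advance by the analytic
// exponential (Rush-Larsen) update toward their voltage-dependent steady
// state, evaluated from lookup tables supplied by R; the voltage solve is
// backward-Euler implicit on the whole tree (Hines elimination), with ohmic
// channel conductances folded into the implicit system and the GHK calcium
// current applied as an explicit source; the single-pool calcium then
// advances by its own exact exponential update.
//
// Units: mV, ms, nA, uS, nF; densities arrive as absolute uS per
// compartment; GHK "conductance" times the mV driving term gives nA.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double CLAMP_G = 1e9; // uS; voltage clamp as a stiff conductance

struct GateTab {
  int expo;
  std::vector<double> vshift; // per compartment, mV
  std::vector<double> xinf;   // steady state on the voltage grid
  std::vector<double> etab;   // exp(-dt/tau) on the voltage grid
};

struct Chan {
  bool ghk;
  double erev;
  std::vector<double> dens;   // uS per compartment
  std::vector<int> active;    // compartments with dens > 0
  std::vector<GateTab> gates;
  std::vector<int> gcol;      // column of each gate in the state matrix
};

static inline double lut(const std::vector<double>& tab, double v,
                         double vmin, double inv_dv, int n) {
  double x = (v - vmin) * inv_dv;
  if (x <= 0.0) return tab[0];
  if (x >= n - 1) return tab[n - 1];
  int k = (int)x;
  double f = x - k;
  return tab[k] + f * (tab[k + 1] - tab[k]);
}

// [[Rcpp::export]]
List engine_run(List em, NumericVector v0, NumericMatrix g0,
                NumericVector ca0, NumericVector inj_nA, int inj_comp,
                IntegerVector rec_comps, int record_every, double dt,
                int clamp_comp, double clamp_v) {
  const IntegerVector parent = em["parent"];
  const NumericVector cm_nF = em["cm_nF"];
  const NumericVector gpas = em["gpas_uS"];
  const double epas = as<double>(em["epas"]);
  const NumericVector gax = em["gax_uS"];
  const double vmin = as<double>(em["vmin"]);
  const double dv = as<double>(em["dv"]);
  const int n = parent.size();
  const int nsteps = inj_nA.size();
  const double inv_dv = 1.0 / dv;

  List chans_in = em["chans"];
  std::vector<Chan> chans;
  int ngate_cols = 0;
  for (int c = 0; c < chans_in.size(); ++c) {
    List ci = chans_in[c];
    Chan ch;
    ch.ghk = as<bool>(ci["ghk"]);
    ch.erev = as<double>(ci["erev"]);
    ch.dens = as<std::vector<double>>(ci["dens_uS"]);
    for (int i = 0; i < n; ++i) if (ch.dens[i] > 0) ch.active.push_back(i);
    List gl = ci["gates"];
    for (int g = 0; g < gl.size(); ++g) {
      List gi = gl[g];
      GateTab gt;
      gt.expo = as<int>(gi["expo"]);
      gt.vshift = as<std::vector<double>>(gi["vshift"]);
      gt.xinf = as<std::vector<double>>(gi["xinf"]);
      std::vector<double> tau = as<std::vector<double>>(gi["tau"]);
      gt.etab.resize(tau.size());
      for (size_t k = 0; k < tau.size(); ++k)
        gt.etab[k] = std::exp(-dt / tau[k]);
      gt.vshift.resize(n, 0.0);
      ch.gates.push_back(gt);
      ch.gcol.push_back(ngate_cols++);
    }
    chans.push_back(ch);
  }
  // calcium
  List cal = em["ca"];
  const IntegerVector ca_on = cal["on"];
  const double ca_tau = as<double>(cal["tau_ms"]);
  const double ca_rest = as<double>(cal["rest_mM"]);
  const double ca_cao = as<double>(cal["cao_mM"]);
  const NumericVector cafac = cal["cafac"]; // nA -> mM/ms influx factor
  const double eca = std::exp(-dt / ca_tau);
  std::vector<double> ghk_fe, ghk_en;
  bool any_ghk = false;
  for (auto& ch : chans) any_ghk = any_ghk || ch.ghk;
  if (any_ghk) {
    ghk_fe = as<std::vector<double>>(em["ghk_fe"]);
    ghk_en = as<std::vector<double>>(em["ghk_en"]);
  }
  const int nfe = (int)ghk_fe.size();

  // state
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<std::vector<double>> gs(ngate_cols, std::vector<double>(n));
  for (int j = 0; j < ngate_cols; ++j)
    for (int i = 0; i < n; ++i) gs[j][i] = g0(i, j);
  std::vector<double> ca(ca0.begin(), ca0.end());

  // static part of the diagonal
  std::vector<double> dstat(n);
  for (int i = 0; i < n; ++i) dstat[i] = cm_nF[i] / dt + gpas[i];
  for (int i = 0; i < n; ++i) {
    if (parent[i] >= 0) {
      dstat[i] += gax[i];
      dstat[parent[i]] += gax[i];
    }
  }

  const int nrec = rec_comps.size();
  const int nrecs = (nsteps - 1) / record_every + 1;
  NumericMatrix vrec(nrecs, nrec), carec(nrecs, nrec);
  NumericVector trec(nrecs), icl(nrecs), irec(nrecs);
  double vmax = -1e30;
  int rrow = 0;

  std::vector<double> d(n), rhs(n), ighk(n, 0.0);

  for (int s = 0; s < nsteps; ++s) {
    // gate update (Rush-Larsen at current voltage)
    for (auto& ch : chans) {
      for (size_t g = 0; g < ch.gates.size(); ++g) {
        GateTab& gt = ch.gates[g];
        std::vector<double>& x = gs[ch.gcol[g]];
        const int nt = (int)gt.xinf.size();
        for (int idx : ch.active) {
          double vv = v[idx] - gt.vshift[idx];
          double xi = lut(gt.xinf, vv, vmin, inv_dv, nt);
          double e = lut(gt.etab, vv, vmin, inv_dv, nt);
          x[idx] = xi + (x[idx] - xi) * e;
        }
      }
    }
    // assemble
    for (int i = 0; i < n; ++i) {
      d[i] = dstat[i];
      rhs[i] = cm_nF[i] / dt * v[i] + gpas[i] * epas;
      ighk[i] = 0.0;
    }
    for (auto& ch : chans) {
      for (int idx : ch.active) {
        double open = 1.0;
        for (size_t g = 0; g < ch.gates.size(); ++g) {
          double x = gs[ch.gcol[g]][idx];
          int e = ch.gates[g].expo;
          double xe = x;
          for (int k = 1; k < e; ++k) xe *= x;
          open *= xe;
        }
        double gd = ch.dens[idx] * open;
        if (ch.ghk) {
          double fe = lut(ghk_fe, v[idx], vmin, inv_dv, nfe);
          double en = lut(ghk_en, v[idx], vmin, inv_dv, nfe);
          double driving = -fe * (1.0 - (ca[idx] / ca_cao) * en); // mV
          double i_nA = gd * driving;
          ighk[idx] += i_nA;
          rhs[idx] -= i_nA;
        } else {
          d[idx] += gd;
          rhs[idx] += gd * ch.erev;
        }
      }
    }
    if (inj_comp >= 0) rhs[inj_comp] += inj_nA[s];
    if (clamp_comp >= 0) {
      d[clamp_comp] += CLAMP_G;
      rhs[clamp_comp] += CLAMP_G * clamp_v;
    }
    // Hines solve: eliminate leaves upward, substitute downward
    for (int i = n - 1; i >= 1; --i) {
      int p = parent[i];
      double f = gax[i] / d[i];
      d[p] -= gax[i] * f;
      rhs[p] += f * rhs[i];
    }
    v[0] = rhs[0] / d[0];
    for (int i = 1; i < n; ++i) v[i] = (rhs[i] + gax[i] * v[parent[i]]) / d[i];
    // calcium
    for (int i = 0; i < n; ++i) {
      if (ca_on[i]) {
        double flux = -ighk[i] * cafac[i]; // mM/ms, inward current raises Ca
        double cinf = ca_rest + flux * ca_tau;
        ca[i] = cinf + (ca[i] - cinf) * eca;
        if (ca[i] < 1e-12) ca[i] = 1e-12;
      }
    }
    for (int i = 0; i < n; ++i) if (v[i] > vmax) vmax = v[i];
    if (s % record_every == 0) {
      trec[rrow] = s * dt;
      irec[rrow] = inj_nA[s];
      for (int r = 0; r < nrec; ++r) {
        vrec(rrow, r) = v[rec_comps[r]];
        carec(rrow, r) = ca[rec_comps[r]];
      }
      if (clamp_comp >= 0)
        icl[rrow] = CLAMP_G * (clamp_v - v[clamp_comp]);
      if (!std::isfinite(v[0]))
        stop("integration failure: non-finite voltage at t = %f ms", s * dt);
      ++rrow;
    }
  }
  NumericVector vend(v.begin(), v.end());
  NumericVector caend(ca.begin(), ca.end());
  NumericMatrix gend(n, ngate_cols);
  for (int j = 0; j < ngate_cols; ++j)
    for (int i = 0; i < n; ++i) gend(i, j) = gs[j][i];
  return List::create(_["t_ms"] = trec, _["v"] = vrec, _["ca"] = carec,
                      _["i_nA"] = irec, _["i_clamp_nA"] = icl,
                      _["v_end"] = vend, _["gates_end"] = gend,
                      _["ca_end"] = caend, _["v_max"] = vmax);
}
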