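// Implicit (backward-Euler) integrator for the branched cable equation with
// Hodgkin-Huxley-style channels.
//
// Gates are advanced by exponential Euler using tabulated steady-state and
// exp(-dt/tau) values on a uniform voltage grid (linear interpolation);
// the voltage step solves the tree-structured linear system by Hines
// elimination (compartments are ordered parent-before-child).  GHK calcium
// flux is tabulated on the same grid and treated explicitly within a step.
// Calcium microdomains are linear pools updated exactly per step.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cable_integrate_cpp(List model, List stim, double dt, double sample_dt,
                         Nullable<List> init_state, bool record_currents,
                         double v_clamp, bool record_gates) {
  const IntegerVector parent = model["parent"];        // 0-based, -1 root
  const NumericVector g_ax   = model["g_ax"];          // uS to parent
  const NumericVector c_nF   = model["c_nF"];
  const NumericVector g_pas  = model["g_pas_uS"];
  const double e_pas         = model["e_pas"];
  const NumericMatrix gbar   = model["gbar"];          // ncomp x nchan (abs)
  const NumericVector area   = model["area_cm2"];
  const IntegerVector ckind  = model["chan_kind"];     // 0 ohmic, 1 ghk
  const NumericVector erev   = model["erev"];
  const IntegerVector cpool  = model["chan_ca_pool"];  // -1 none,0 sk,1 ano
  const IntegerVector csrc   = model["chan_ca_source"];// -1 none,0 cal,1 cat
  const NumericVector hill_n = model["hill_n"];
  const NumericVector ec50   = model["ec50_uM"];
  const IntegerVector gchan  = model["gate_chan"];     // gate -> channel
  const IntegerVector gpow   = model["gate_pow"];
  const NumericMatrix ginf   = model["gate_inf_tab"];  // ngate x nv
  const NumericMatrix gtau   = model["gate_tau_tab"];
  const NumericVector ghk_tab = model["ghk_tab"];      // nv
  const double v0 = model["v_grid_v0"], dvg = model["v_grid_dv"];
  const double depth_um = model["ca_depth_um"];
  const double ca_rest = model["ca_rest_uM"];
  const NumericVector ca_frac = model["ca_fraction"];
  const NumericVector ca_tau  = model["ca_tau_ms"];

  const int ncomp = parent.size();
  const int nchan = gbar.ncol();
  const int ngate = gchan.size();
  const int nv = ginf.ncol();

  const int inj_comp = stim["inj_comp"];
  const double bias_nA = as<double>(stim["bias_pA"]) * 1e-3;
  const double step_nA = as<double>(stim["step_pA"]) * 1e-3;
  const double onset = stim["onset_ms"], dur = stim["dur_ms"];
  const double total = stim["total_ms"];
  const int rec_comp = stim["record_comp"];

  const bool clamp = R_finite(v_clamp);

  // exp(-dt/tau) tables for this dt
  NumericMatrix gexp(ngate, nv);
  for (int g = 0; g < ngate; ++g)
    for (int j = 0; j < nv; ++j)
      gexp(g, j) = std::exp(-dt / gtau(g, j));
  double ca_exp[3], ca_k;
  for (int p = 0; p < 3; ++p) ca_exp[p] = std::exp(-dt / ca_tau[p]);
  ca_k = 1e4 / (2.0 * 96485.332 * depth_um);  // mM cm^2 / (mA ms)

  // per-compartment active-gate mask (gbar == 0 -> gate frozen, unused)
  std::vector<char> gact(static_cast<size_t>(ncomp) * ngate);
  for (int i = 0; i < ncomp; ++i)
    for (int g = 0; g < ngate; ++g)
      gact[static_cast<size_t>(i) * ngate + g] = gbar(i, gchan[g]) > 0;

  // state
  NumericVector V(ncomp);
  NumericMatrix gates(ncomp, ngate);
  NumericMatrix ca(ncomp, 3);
  if (init_state.isNotNull()) {
    List st(init_state);
    NumericVector v_in = st["v"];
    NumericMatrix g_in = st["gates"], c_in = st["ca"];
    if (v_in.size() != ncomp) stop("init state size mismatch");
    V = clone(v_in); gates = clone(g_in); ca = clone(c_in);
  } else {
    double vi = as<double>(model["v_init"]);
    for (int i = 0; i < ncomp; ++i) {
      V[i] = vi;
      double u = (vi - v0) / dvg;
      int j = std::max(0, std::min(nv - 2, static_cast<int>(std::floor(u))));
      double f = u - j;
      for (int g = 0; g < ngate; ++g)
        gates(i, g) = ginf(g, j) * (1 - f) + ginf(g, j + 1) * f;
      for (int p = 0; p < 3; ++p) ca(i, p) = ca_rest;
    }
  }
  if (clamp) for (int i = 0; i < ncomp; ++i) V[i] = v_clamp;

  const int nstep = static_cast<int>(std::round(total / dt));
  const int stride = std::max(1, static_cast<int>(std::round(sample_dt / dt)));
  const int nsamp = nstep / stride + 1;

  NumericVector t_out(nsamp), v_out(nsamp);
  NumericMatrix cur_out = record_currents ? NumericMatrix(nsamp, nchan)
                                          : NumericMatrix(1, 1);
  NumericMatrix gates_out = record_gates ? NumericMatrix(nsamp, ngate)
                                         : NumericMatrix(1, 1);
  int isamp = 0;
  t_out[0] = 0; v_out[0] = V[rec_comp];
  if (record_gates) for (int g = 0; g < ngate; ++g) gates_out(0, g) = gates(rec_comp, g);
  isamp = 1;

  std::vector<double> diag(ncomp), rhs(ncomp), i_cal(ncomp), i_cat(ncomp);
  std::vector<double> open_c(nchan);

  for (int s = 1; s <= nstep; ++s) {
    double tnow = s * dt;
    double inj = bias_nA + ((tnow > onset && tnow <= onset + dur) ? step_nA : 0.0);

    bool sample_now = (s % stride) == 0;
    for (int i = 0; i < ncomp; ++i) {
      double v = V[i];
      double u = (v - v0) / dvg;
      int j = std::max(0, std::min(nv - 2, static_cast<int>(std::floor(u))));
      double f = u - j;
      const char* am = &gact[static_cast<size_t>(i) * ngate];
      // gate update (exponential Euler at frozen v)
      for (int g = 0; g < ngate; ++g) {
        if (!am[g]) continue;
        double inf = ginf(g, j) * (1 - f) + ginf(g, j + 1) * f;
        double ee  = gexp(g, j) * (1 - f) + gexp(g, j + 1) * f;
        gates(i, g) = inf + (gates(i, g) - inf) * ee;
      }
      // open fractions per channel
      for (int c = 0; c < nchan; ++c) open_c[c] = 1.0;
      for (int g = 0; g < ngate; ++g) {
        if (!am[g]) continue;
        double x = gates(i, g);
        double xp = x;
        for (int k = 1; k < gpow[g]; ++k) xp *= x;
        open_c[gchan[g]] *= xp;
      }
      // currents
      double gtot = g_pas[i], brhs = g_pas[i] * e_pas;
      double ghkv = ghk_tab[j] * (1 - f) + ghk_tab[j + 1] * f;
      double icalL = 0, icatL = 0;
      for (int c = 0; c < nchan; ++c) {
        double gb = gbar(i, c);
        if (gb <= 0) { if (record_currents && i == rec_comp && sample_now) cur_out(isamp, c) = 0; continue; }
        double op = open_c[c];
        if (cpool[c] >= 0) {
          double cav = ca(i, cpool[c]);
          double num = std::pow(cav, hill_n[c]);
          op *= num / (num + std::pow(ec50[c], hill_n[c]));
        }
        double i_nA;
        if (ckind[c] == 0) {
          double gc = gb * op;           // uS
          gtot += gc; brhs += gc * erev[c];
          i_nA = gc * (v - erev[c]);
        } else {
          i_nA = gb * op * ghkv;         // gb = P*area*1e6
          brhs -= i_nA;
          double dens = i_nA / (area[i] * 1e6);  // mA/cm^2
          if (csrc[c] == 0) icalL += dens; else if (csrc[c] == 1) icatL += dens;
        }
        if (record_currents && i == rec_comp && sample_now) cur_out(isamp, c) = i_nA;
      }
      i_cal[i] = icalL; i_cat[i] = icatL;
      diag[i] = c_nF[i] / dt + gtot;
      rhs[i] = c_nF[i] / dt * v + brhs;
      // calcium pools: exact update with this step's flux
      for (int p = 0; p < 3; ++p) {
        double src = (p < 2) ? icalL : icatL;
        double drive = -ca_frac[p] * src * ca_k * 1e3;  // uM/ms
        if (drive < 0) drive = 0;
        double target = ca_rest + drive * ca_tau[p];
        ca(i, p) = target + (ca(i, p) - target) * ca_exp[p];
      }
    }

    if (!clamp) {
      rhs[inj_comp] += inj;
      // add axial terms
      for (int i = 1; i < ncomp; ++i) {
        int p = parent[i];
        diag[i] += g_ax[i];
        diag[p] += g_ax[i];
      }
      // Hines elimination (children have larger indices)
      for (int i = ncomp - 1; i >= 1; --i) {
        int p = parent[i];
        double f = g_ax[i] / diag[i];
        diag[p] -= g_ax[i] * f;
        rhs[p] += rhs[i] * f;
      }
      V[0] = rhs[0] / diag[0];
      for (int i = 1; i < ncomp; ++i)
        V[i] = (rhs[i] + g_ax[i] * V[parent[i]]) / diag[i];
      if (std::abs(V[rec_comp]) > 200.0 || !R_finite(V[rec_comp]))
        stop("numerical divergence at t = %f ms", tnow);
    }

    if (sample_now) {
      t_out[isamp] = tnow; v_out[isamp] = V[rec_comp];
      if (record_gates)
        for (int g = 0; g < ngate; ++g) gates_out(isamp, g) = gates(rec_comp, g);
      ++isamp;
    }
  }

  List state = List::create(_["v"] = V, _["gates"] = gates, _["ca"] = ca);
  List out = List::create(_["t"] = t_out, _["v"] = v_out, _["state"] = state);
  if (record_currents) out["currents"] = cur_out;
  if (record_gates) out["gates"] = gates_out;
  return out;
}
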